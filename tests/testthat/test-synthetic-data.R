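test_that("generators are deterministic under a fixed config and seed", {
  st1 <- small_planted_study(seed = 4)
  st2 <- small_planted_study(seed = 4)
  expect_identical(st1$annotation, st2$annotation)
  expect_identical(st1$sites, st2$sites)
  expect_identical(st1$truth$targets, st2$truth$targets)
  expect_identical(st1$compendium$exprs, st2$compendium$exprs)
  st3 <- small_planted_study(seed = 5)
  expect_false(identical(st1$compendium$exprs, st3$compendium$exprs))
})

test_that("annotation partitions genes into operons and respects geometry", {
  cfg <- sim_config(n_genes = 10, n_operons = 3, seed = 1)
  ann <- sim_annotation(cfg)
  expect_equal(nrow(ann), 10L)
  expect_equal(length(unique(ann$operon_id)), 3L)
  expect_equal(sum(table(ann$operon_id)), 10L)
  # one operon id per gene, ranks unique within operon, shared strand
  for (op in split(ann, ann$operon_id)) {
    expect_equal(sort(op$operon_rank), seq_len(nrow(op)))
    expect_length(unique(op$strand), 1L)
  }
  # gene bodies never overlap
  ord <- ann[order(ann$replicon, ann$start), ]
  expect_true(all(diff(ord$start) > 0))
  expect_true(all(ord$start[-1] > ord$end[-nrow(ord)]))
  # start codon at the strand-appropriate body end
  expect_true(all(ifelse(ann$strand == "+", ann$start_codon == ann$start,
                         ann$start_codon == ann$end)))
})

test_that("mean inter-operon gap tracks the configured gap parameter", {
  cfg <- sim_config(seed = 3) # default 2400 genes / 1400 operons
  ann <- sim_annotation(cfg)
  ord <- ann[order(ann$start), ]
  boundary <- ord$operon_id[-1] != ord$operon_id[-nrow(ord)]
  gaps <- (ord$start[-1] - ord$end[-nrow(ord)])[boundary]
  expect_gt(length(gaps), 1000)
  expect_lt(abs(mean(gaps) - cfg$mean_intergenic_gap),
            0.1 * cfg$mean_intergenic_gap)
})

test_that("fixed replicon length errors when genes cannot be packed", {
  expect_error(sim_annotation(sim_config(n_genes = 100, n_operons = 50,
                                         replicon_length = 1000, seed = 1)),
               "packed")
})

test_that("annotation survives a GFF3 + operon table round trip", {
  cfg <- sim_config(n_genes = 30, n_operons = 18, seed = 7)
  ann <- sim_annotation(cfg)
  gff <- tempfile(fileext = ".gff3"); ops <- tempfile(fileext = ".tsv")
  write_annotation(ann, gff, ops)
  back <- read_annotation(gff, ops)
  for (col in c("gene_id", "replicon", "strand", "start", "end",
                "start_codon", "operon_id", "operon_rank")) {
    expect_equal(back[[col]], ann[[col]], info = col)
  }
})

test_that("planted binding sites are significant and inside promoters", {
  st <- small_planted_study(seed = 9, decoys_per_tf = 0,
                            genic_decoys_per_tf = 0)
  expect_true(all(st$sites$pvalue <= 0.01))
  ts <- target_sets(assign_targets(st$sites, st$annotation))
  for (tf in st$truth$tfs) {
    expect_setequal(ts[[tf]], st$truth$targets[[tf]])
  }
})

test_that("a non-significant decoy site never creates a target", {
  ann <- make_annotation(data.frame(
    gene_id = "g3", replicon = "chr1", strand = "+",
    start = 1000L, end = 1900L))
  sites <- make_sites("tfA", "chr1", 900L, 0.5)
  tm <- assign_targets(sites, ann)
  expect_equal(nrow(tm), 0L)
})

test_that("planted sites are recovered at high rate under jitter", {
  cfg <- sim_config(n_genes = 600, n_operons = 360, n_tfs = 1,
                    targets_per_tf = c(100, 100), jitter_sd = 25,
                    decoys_per_tf = 0, genic_decoys_per_tf = 0, seed = 21)
  ann <- sim_annotation(cfg)
  tr <- sim_truth(cfg, ann)
  sites <- sim_binding_sites(cfg, ann, tr)
  ts <- target_sets(assign_targets(sites, ann))
  recovered <- length(intersect(ts[[tr$tfs]], tr$targets[[tr$tfs]]))
  expect_gte(recovered / length(tr$targets[[tr$tfs]]), 0.95)
})

test_that("coupled-gene count follows fraction_coupled exactly", {
  st <- small_planted_study(seed = 13)
  tr <- st$truth
  for (i in seq_len(nrow(tr$planted))) {
    key <- paste(tr$planted$tf_id[i], tr$planted$condition_set_id[i],
                 sep = "|")
    n_targets <- length(tr$targets[[tr$planted$tf_id[i]]])
    expect_length(tr$coupled[[key]],
                  round(tr$planted$fraction_coupled[i] * n_targets))
    expect_true(all(tr$coupled[[key]] %in% tr$targets[[tr$planted$tf_id[i]]]))
  }
})

test_that("noiseless planted couplings give perfect rank correlation", {
  st <- small_planted_study(seed = 2, noise_sd = 0, missing_rate = 0)
  tr <- st$truth
  for (i in seq_len(nrow(tr$planted))) {
    tf <- tr$planted$tf_id[i]; cs <- tr$planted$condition_set_id[i]
    coupled <- setdiff(tr$coupled[[paste(tf, cs, sep = "|")]], tf)
    r <- per_gene_correlations(st$compendium, tf, coupled, cs)
    expected <- if (tr$planted$role[i] == "activator") 1 else -1
    expect_equal(unname(r), rep(expected, length(r)), tolerance = 1e-12)
  }
})

test_that("coupled-gene correlation matches the analytic attenuation", {
  # rho = beta * sd(TF) / sqrt(beta^2 sd(TF)^2 + noise_sd^2), Pearson
  pr <- data.frame(tf = 1, condition_set = 1, role = "activator",
                   beta = 0.8)
  cfg <- sim_config(n_genes = 800, n_operons = 500, n_tfs = 1,
                    n_condition_sets = 3, arrays_per_set = c(12, 12),
                    targets_per_tf = c(150, 150), planted_regulons = pr,
                    noise_sd = 0.25, missing_rate = 0, seed = 31)
  ann <- sim_annotation(cfg)
  tr <- sim_truth(cfg, ann)
  comp <- sim_compendium(cfg, tr)
  tf <- tr$planted$tf_id; cs <- tr$planted$condition_set_id
  coupled <- setdiff(tr$coupled[[paste(tf, cs, sep = "|")]], tf)
  tf_sd <- sd(comp$exprs[tf, comp$sets[[cs]]])
  rho <- 0.8 * tf_sd / sqrt(0.8^2 * tf_sd^2 + 0.25^2)
  r <- per_gene_correlations(comp, tf, coupled, cs, method = "pearson")
  expect_lt(abs(mean(abs(r)) - rho), 0.05)
})

test_that("residue-profile generator respects groups and alphabet", {
  spec <- data.frame(
    tf = paste0("tf", 1:6),
    group = rep(c("A", "B"), each = 3),
    consensus = rep(c("ARNDCQEGH", "ILKMFPSTW"), each = 3),
    n_mutations = 0L)
  prof <- sim_residue_profiles(spec, seed = 1)
  expect_identical(unname(prof), spec$consensus)
  d <- residue_similarity(prof)$distance
  expect_true(all(d[1:3, 1:3] == 0))
  cl <- effector_clusters(prof, k = 2)
  expect_equal(length(unique(cl$cluster[1:3])), 1L)
  expect_equal(length(unique(cl$cluster[4:6])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[4])
  expect_error(sim_residue_profiles(data.frame(
    tf = "x", group = "A", consensus = "AAAAAAAAZ")), "alphabet")
})

test_that("mutated profiles still recover the planted partition", {
  spec <- data.frame(
    tf = paste0("tf", 1:8),
    group = rep(c("A", "B"), each = 4),
    consensus = rep(c("ARNDCQEGH", "ILKMFPSTW"), each = 4),
    n_mutations = 1L)
  hits <- 0L
  for (s in 1:100) {
    prof <- sim_residue_profiles(spec, seed = s)
    cl <- effector_clusters(prof, k = 2)
    ok <- length(unique(cl$cluster[1:4])) == 1L &&
      length(unique(cl$cluster[5:8])) == 1L &&
      cl$cluster[1] != cl$cluster[5]
    hits <- hits + ok
  }
  expect_gte(hits, 95L)
})

test_that("growth-curve generator validates parameters", {
  expect_error(sim_growth_curves(data.frame(strain = "a", K = -1, r = 0.3,
                                            lag = 0)), "positive")
  expect_error(sim_growth_curves(data.frame(strain = "a", K = 2, r = 0,
                                            lag = 0)), "positive")
  g <- sim_growth_curves(data.frame(strain = "a", K = 2, r = 0.3, lag = 5),
                         noise_sd = 0.02, seed = 1)
  expect_equal(nrow(g), 2 * 3 * length(seq(0, 96, 0.5)))
  expect_true(all(g$od600 >= 0.01))
})
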