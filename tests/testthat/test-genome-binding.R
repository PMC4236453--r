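plus_gene <- make_annotation(data.frame(
  gene_id = "g1", replicon = "chr1", strand = "+",
  start = 1000L, end = 1900L))

minus_gene <- make_annotation(data.frame(
  gene_id = "m1", replicon = "chr1", strand = "-",
  start = 1000L, end = 1900L))

test_that("promoter windows are strand-aware with inclusive bounds", {
  hit <- function(ann, pos, p = 0.005) {
    nrow(assign_targets(make_sites("t", "chr1", pos, p), ann))
  }
  # + strand, start codon 1000: window [750, 1050]
  expect_equal(hit(plus_gene, 900L), 1L)
  expect_equal(hit(plus_gene, 750L), 1L)
  expect_equal(hit(plus_gene, 749L), 0L) # 251 bp upstream
  expect_equal(hit(plus_gene, 1050L), 1L)
  expect_equal(hit(plus_gene, 1051L), 0L)
  # - strand, start codon 1900: window [1850, 2150]
  expect_equal(hit(minus_gene, 2150L), 1L)
  expect_equal(hit(minus_gene, 2151L), 0L)
  expect_equal(hit(minus_gene, 1850L), 1L)
  expect_equal(hit(minus_gene, 1849L), 0L)
  # p-value cutoff is inclusive at 0.01
  expect_equal(hit(plus_gene, 900L, 0.01), 1L)
  expect_equal(hit(plus_gene, 900L, 0.011), 0L)
})

test_that("operon members downstream of a promoter hit are propagated", {
  ann <- make_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"), replicon = "chr1", strand = "+",
    start = c(1000L, 2000L, 3000L), end = c(1900L, 2900L, 3900L),
    operon_id = "op1", operon_rank = 1:3))
  tm <- assign_targets(make_sites("t", "chr1", 900L, 0.01), ann)
  expect_setequal(tm$gene_id, c("g1", "g2", "g3"))
  expect_equal(tm$provenance[tm$gene_id == "g1"], "direct-promoter")
  expect_equal(tm$provenance[tm$gene_id == "g2"], "operon-propagated")
  # a hit in g2's promoter propagates to g3 but not back to g1
  tm2 <- assign_targets(make_sites("t", "chr1", 1950L, 0.01), ann)
  expect_setequal(tm2$gene_id, c("g2", "g3"))
})

test_that("assign_targets validates inputs", {
  expect_error(assign_targets(make_sites("t", "chrX", 10L, 0.01), plus_gene),
               "unknown replicon")
  expect_error(assign_targets(make_sites("t", "chr1", 10L, 0.01), plus_gene,
                              upstream = -1), "non-negative")
})

test_that("raising p_max never removes targets", {
  st <- small_planted_study(seed = 6)
  strict <- target_sets(assign_targets(st$sites, st$annotation,
                                       p_max = 0.01))
  loose <- target_sets(assign_targets(st$sites, st$annotation, p_max = 0.5))
  for (tf in names(strict)) {
    expect_true(all(strict[[tf]] %in% loose[[tf]]))
  }
})

test_that("peak context fractions match direct arithmetic", {
  ann <- make_annotation(data.frame(
    gene_id = "g1", replicon = "chr1", strand = "+",
    start = 41L, end = 900L), replicon_lengths = c(chr1 = 1000))
  res <- peak_context_fractions(make_sites("t", "chr1", c(100L, 500L), 0.5),
                                ann)
  expect_equal(unname(res$genome["genic"]), 0.86)
  expect_equal(sum(res$genome), 1)
  expect_equal(unname(res$sites["genic"]), 1.0)
  res2 <- peak_context_fractions(make_sites("t", "chr1", c(10L, 950L), 0.5),
                                 ann)
  expect_equal(unname(res2$sites["genic"]), 0)
})

test_that("uniform random sites land genic at the genome fraction", {
  cfg <- sim_config(n_genes = 500, n_operons = 300, seed = 17)
  ann <- sim_annotation(cfg)
  rl <- attr(ann, "replicon_lengths")
  set.seed(1)
  n <- 4000
  sites <- make_sites("t", "chr1", sample.int(as.integer(rl["chr1"]), n,
                                              replace = TRUE), 0.5)
  res <- peak_context_fractions(sites, ann)
  p <- unname(res$genome["genic"])
  expect_lt(abs(res$sites[["genic"]] - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("target overlap matches the closed form and enumeration", {
  u <- paste0("g", 1:10)
  ov <- target_overlap(u[1:4], u[1:5], u)
  expect_equal(ov$k, 4L)
  expect_equal(ov$percent_overlap, 100)
  expect_equal(ov$pvalue, 5 / 210)
  # exhaustive oracle: draw all C(10,5) subsets as B, count overlap >= 4
  bs <- combn(10, 5)
  exact <- mean(apply(bs, 2, function(b) length(intersect(1:4, b)) >= 4))
  expect_equal(ov$pvalue, exact)
  # symmetry of percent overlap, identical and disjoint cases
  ov_ba <- target_overlap(u[1:5], u[1:4], u)
  expect_equal(ov$percent_overlap, ov_ba$percent_overlap)
  self <- target_overlap(u[1:4], u[1:4], u)
  expect_equal(self$k, 4L)
  expect_equal(self$percent_overlap, 100)
  dis <- target_overlap(u[1:5], u[6:10], u)
  expect_equal(dis$k, 0L)
  expect_equal(dis$pvalue, 1)
  expect_error(target_overlap(u[1:2], u[1:2], character(0)), "universe")
  expect_error(target_overlap(c(u[1], "zz"), u[1:2], u), "subsets")
})

test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  set.seed(42)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    u <- paste0("g", seq_len(N))
    a <- sample(u, sample(2:(N - 1), 1))
    nb <- sample(2:(N - 1), 1)
    b <- sample(u, nb)
    k <- length(intersect(a, b))
    bs <- combn(N, nb)
    exact <- mean(apply(bs, 2, function(idx)
      length(intersect(a, u[idx])) >= k))
    expect_equal(target_overlap(a, b, u)$pvalue, exact, tolerance = 1e-12)
  }
})

test_that("multi-TF binding enrichment matches its exhaustive oracle", {
  u <- paste0("g", 1:10)
  maps <- list(tfA = u[1:5], tfB = u[1:5])
  res <- multi_binding_enrichment(maps, u, min_tfs = 2, n_perm = 20000,
                                  seed = 1)
  expect_equal(res$observed, 5L)
  # oracle: both 5-sets redrawn; count of shared genes >= 5 iff identical
  subsets <- combn(10, 5)
  memb <- apply(subsets, 2, function(s) as.integer(1:10 %in% s))
  counts <- crossprod(memb) # pairwise intersection sizes
  exact <- mean(counts >= 5)
  expect_equal(exact, 1 / 252)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$pvalue - exact), 3 * se + 1 / 20001)
})

test_that("multi-TF enrichment handles disjoint maps and the p floor", {
  u <- paste0("g", 1:20)
  dis <- multi_binding_enrichment(list(a = u[1:5], b = u[6:10]), u,
                                  n_perm = 200, seed = 1)
  expect_equal(dis$observed, 0L)
  expect_equal(dis$pvalue, 1)
  # observed count that no null redraw can reach gives the estimator floor
  full <- multi_binding_enrichment(list(a = u[1:3], b = u[1:3],
                                        c = u[1:3]), u,
                                   min_tfs = 3, n_perm = 1000, seed = 1)
  expect_equal(full$observed, 3L)
  expect_gte(full$pvalue, 1 / 1001)
  expect_error(multi_binding_enrichment(list(a = u), u, min_tfs = 1),
               "min_tfs")
  expect_error(multi_binding_enrichment(list(a = c(u, "zz")), u[1:3]),
               "larger than the universe")
})
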