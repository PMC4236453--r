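#' Configuration for the synthetic FFRP study generator
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' list. The defaults emulate the data regime of the archaeal FFRP study the
#' pipeline was designed around: a ~2,400-gene genome organised into operons,
#' 8 transcription factors with overlapping target repertoires (34-356
#' targets each), and an expression compendium of ~35 environmental
#' condition sets of 6-20 two-colour arrays each (~460 arrays total), with
#' expression stored as log2 ratios against a common reference.
#'
#' @param n_genes number of genes in the genome.
#' @param n_operons number of transcription units; every gene belongs to
#'   exactly one operon (singletons allowed). The default gives a mean operon
#'   size of ~1.7 genes, typical of prokaryotic genomes.
#' @param n_tfs number of transcription factors; TFs are themselves genes.
#' @param n_condition_sets number of environmental condition sets.
#' @param arrays_per_set integer range (length 2) of arrays per condition set.
#' @param targets_per_tf integer range of operon-head targets drawn per TF;
#'   after operon expansion (mean operon size ~1.7) the default yields
#'   total target counts spanning roughly the 34-356 range observed for
#'   real FFRP binding maps.
#' @param planted_regulons `NULL`, or a data frame with columns `tf`
#'   (TF index 1..n_tfs), `condition_set` (set index), `role`
#'   (`"activator"`/`"repressor"`), and optionally `beta` (coupling strength,
#'   dimensionless multiplier on the TF profile) and `fraction_coupled`
#'   (fraction of the TF's targets that actually respond in that set).
#' @param beta,fraction_coupled defaults for planted regulons that omit them.
#' @param noise_sd standard deviation of i.i.d. Gaussian array noise
#'   (log2-ratio units).
#' @param tf_amp half-range of a planted TF's induction within its planted
#'   condition set (log2 units). The TF profile spans `[0, 2*tf_amp]` there,
#'   so a planted TF always exceeds the 1.75-fold-change filter
#'   (2*tf_amp >= log2(1.75)) by construction.
#' @param tf_shift_sd sd of the per-(TF, set) mean expression shift in
#'   unplanted sets (log2 units).
#' @param tf_profile_sd sd of a TF's array-to-array variation within
#'   unplanted sets (log2 units).
#' @param responder_prob,responder_sd probability that a background gene
#'   responds to a given condition set, and the sd of its response
#'   amplitude (log2 units). Responders follow a set-specific latent
#'   condition profile independent of any TF, emulating the other
#'   co-regulated modules that populate a real compendium.
#' @param missing_rate fraction of expression values set missing, to exercise
#'   pairwise-complete correlation handling.
#' @param mean_gene_length,mean_intergenic_gap genome geometry (bp); gaps
#'   between operons are 50 bp plus an exponential with the stated mean.
#' @param n_replicons number of replicons (chromosome + plasmids).
#' @param replicon_length optional fixed replicon length (bp); an error is
#'   raised if the genes cannot be packed into it.
#' @param jitter_sd sd (bp) of binding-site placement around the promoter
#'   centre, emulating ~50 bp peak-calling resolution.
#' @param decoys_per_tf,genic_decoys_per_tf numbers of non-significant
#'   (p > 0.01) intergenic decoy sites and significant gene-body sites per TF.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [sim_annotation()], [sim_truth()], [sim_compendium()]
#' @export
sim_config <- function(n_genes = 2400, n_operons = 1400, n_tfs = 8,
                       n_condition_sets = 35, arrays_per_set = c(6L, 20L),
                       targets_per_tf = c(20L, 210L),
                       planted_regulons = NULL,
                       beta = 0.8, fraction_coupled = 0.75,
                       noise_sd = 0.25, tf_amp = 1.0, tf_shift_sd = 0.5,
                       tf_profile_sd = 0.6, responder_prob = 0.3,
                       responder_sd = 0.6, missing_rate = 0.02,
                       mean_gene_length = 900, mean_intergenic_gap = 150,
                       n_replicons = 1, replicon_length = NULL,
                       jitter_sd = 25, decoys_per_tf = 25,
                       genic_decoys_per_tf = 10, seed = 1L) {
  cfg <- list(
    n_genes = .assert_scalar_count(n_genes, "n_genes"),
    n_operons = .assert_scalar_count(n_operons, "n_operons"),
    n_tfs = .assert_scalar_count(n_tfs, "n_tfs"),
    n_condition_sets = .assert_scalar_count(n_condition_sets,
                                            "n_condition_sets"),
    arrays_per_set = as.integer(arrays_per_set),
    targets_per_tf = as.integer(targets_per_tf),
    planted_regulons = planted_regulons,
    beta = beta, fraction_coupled = fraction_coupled,
    noise_sd = noise_sd, tf_amp = tf_amp, tf_shift_sd = tf_shift_sd,
    tf_profile_sd = tf_profile_sd, responder_prob = responder_prob,
    responder_sd = responder_sd, missing_rate = missing_rate,
    mean_gene_length = mean_gene_length,
    mean_intergenic_gap = mean_intergenic_gap,
    n_replicons = .assert_scalar_count(n_replicons, "n_replicons"),
    replicon_length = replicon_length,
    jitter_sd = jitter_sd, decoys_per_tf = as.integer(decoys_per_tf),
    genic_decoys_per_tf = as.integer(genic_decoys_per_tf),
    seed = as.integer(seed))
  if (cfg$n_genes < cfg$n_operons) {
    stop("n_genes must be >= n_operons", call. = FALSE)
  }
  if (length(cfg$arrays_per_set) != 2L || any(cfg$arrays_per_set < 2L) ||
      diff(cfg$arrays_per_set) < 0) {
    stop("arrays_per_set must be an increasing range of counts >= 2",
         call. = FALSE)
  }
  if (length(cfg$targets_per_tf) != 2L || any(cfg$targets_per_tf < 1L)) {
    stop("targets_per_tf must be a range of positive counts", call. = FALSE)
  }
  if (!is.finite(cfg$beta)) stop("beta must be finite", call. = FALSE)
  if (cfg$fraction_coupled <= 0 || cfg$fraction_coupled > 1) {
    stop("fraction_coupled must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("noise_sd must be >= 0 and missing_rate in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_regulons)) {
    pr <- planted_regulons
    stopifnot(is.data.frame(pr),
              all(c("tf", "condition_set", "role") %in% names(pr)))
    if (!all(pr$role %in% c("activator", "repressor"))) {
      stop("planted roles must be 'activator' or 'repressor'", call. = FALSE)
    }
    if (any(pr$tf < 1 | pr$tf > cfg$n_tfs) ||
        any(pr$condition_set < 1 | pr$condition_set > cfg$n_condition_sets)) {
      stop("planted regulon indexes an unknown TF or condition set",
           call. = FALSE)
    }
    if (is.null(pr$beta)) pr$beta <- cfg$beta
    if (is.null(pr$fraction_coupled)) pr$fraction_coupled <- cfg$fraction_coupled
    if (any(!is.finite(pr$beta))) stop("planted beta must be finite",
                                       call. = FALSE)
    if (any(pr$fraction_coupled <= 0 | pr$fraction_coupled > 1)) {
      stop("planted fraction_coupled must lie in (0, 1]", call. = FALSE)
    }
    cfg$planted_regulons <- pr
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation with operon structure
#'
#' Genes are packed left to right on each replicon. Genes are grouped into
#' operons whose members are contiguous, share a strand, and are separated by
#' short (5-40 bp) gaps; operons are separated by intergenic gaps of
#' 50 bp plus an exponential with mean `mean_intergenic_gap - 50`. Gene
#' bodies never overlap. The start codon sits at the strand-appropriate end
#' of the body (left end on `+`, right end on `-`), and `operon_rank` counts
#' along the direction of transcription.
#'
#' @param config a [sim_config()].
#' @return a data frame (class `gene_annotation`) with columns `gene_id`,
#'   `replicon`, `strand`, `start`, `end`, `start_codon`, `operon_id`,
#'   `operon_rank`, and a `replicon_lengths` attribute (named numeric).
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  # random composition of n genes into n_operons non-empty operons
  k <- config$n_operons
  sizes <- if (k == 1L) n else
    diff(c(0L, sort(sample.int(n - 1L, k - 1L)), n))
  # operons distributed across replicons round-robin
  rep_of_operon <- rep_len(seq_len(config$n_replicons), k)
  gene_len <- pmax(150L, round(rgamma(n, shape = 4,
                                      scale = config$mean_gene_length / 4)))
  gap_mean <- max(config$mean_intergenic_gap - 50, 1)
  rows <- vector("list", k)
  gi <- 0L
  pos <- integer(config$n_replicons)
  pos[] <- 1L
  for (op in seq_len(k)) {
    m <- sizes[op]
    rp <- rep_of_operon[op]
    strand <- sample(c("+", "-"), 1L)
    starts <- ends <- integer(m)
    p <- pos[rp] + round(50 + rexp(1L, rate = 1 / gap_mean))
    for (j in seq_len(m)) {
      starts[j] <- p
      ends[j] <- p + gene_len[gi + j] - 1L
      p <- ends[j] + sample(5:40, 1L)
    }
    pos[rp] <- ends[m]
    rank <- if (strand == "+") seq_len(m) else rev(seq_len(m))
    rows[[op]] <- data.frame(
      gene_id = sprintf("g%04d", gi + seq_len(m)),
      replicon = sprintf("chr%d", rp),
      strand = strand,
      start = starts, end = ends,
      start_codon = if (strand == "+") starts else ends,
      operon_id = sprintf("op%04d", op),
      operon_rank = rank,
      stringsAsFactors = FALSE)
    gi <- gi + m
  }
  ann <- do.call(rbind, rows)
  rl <- pos + 500
  names(rl) <- sprintf("chr%d", seq_len(config$n_replicons))
  if (!is.null(config$replicon_length)) {
    if (any(pos > config$replicon_length)) {
      stop("genes cannot be packed into replicon_length; increase it",
           call. = FALSE)
    }
    rl[] <- config$replicon_length
  }
  attr(ann, "replicon_lengths") <- rl
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Ground truth for a synthetic study: TFs, target sets and planted regulons
#'
#' Picks `n_tfs` genes as the transcription factors, draws each TF's
#' operon-head targets from a shared pool (so target sets overlap, as in
#' real paralogous TF families), expands heads to full operons, and attaches
#' the planted condition-specific couplings with their per-gene
#' coupled/uncoupled flags. The number of coupled genes in a planted regulon
#' is exactly `round(fraction_coupled * n_targets)`.
#'
#' @param config a [sim_config()].
#' @param annotation output of [sim_annotation()] for the same config.
#' @return a list (class `sim_truth`) with elements `tfs` (TF gene ids),
#'   `target_heads`, `targets` (lists keyed by TF), `condition_sets`,
#'   `planted` (data frame incl. resolved ids) and `coupled`
#'   (list keyed `"tf|set"`).
#' @export
sim_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  heads <- annotation$gene_id[annotation$operon_rank == 1L]
  # restrict plantable heads to genes with an unambiguous promoter: a site
  # jittered up to 3 sd around the promoter centre must not reach any other
  # gene's window (divergent gene pairs share intergenic space and would
  # otherwise soak up each other's sites)
  heads <- intersect(heads, .unambiguous_promoters(annotation,
                                                   3 * config$jitter_sd))
  tfs <- sort(sample(annotation$gene_id, config$n_tfs))
  # TF genes never appear in target sets: a TF's expression row is its
  # regulator profile, so it cannot double as a planted target value
  tf_operons <- annotation$operon_id[annotation$gene_id %in% tfs]
  heads <- heads[!annotation$operon_id[match(heads, annotation$gene_id)]
                 %in% tf_operons]
  hi <- config$targets_per_tf
  pool_size <- min(length(heads), max(round(1.5 * hi[2L]), hi[2L]))
  pool <- sample(heads, pool_size)
  members <- split(annotation$gene_id, annotation$operon_id)
  head_operon <- annotation$operon_id[match(heads, annotation$gene_id)]
  names(head_operon) <- heads
  target_heads <- targets <- list()
  for (tf in tfs) {
    nt <- if (hi[1L] == hi[2L]) hi[1L] else sample(hi[1L]:hi[2L], 1L)
    th <- sample(pool, min(nt, length(pool)))
    target_heads[[tf]] <- sort(th)
    targets[[tf]] <- sort(unique(unlist(members[head_operon[th]],
                                        use.names = FALSE)))
  }
  sets <- sprintf("CS%02d", seq_len(config$n_condition_sets))
  planted <- config$planted_regulons
  coupled <- list()
  if (!is.null(planted)) {
    planted$tf_id <- tfs[planted$tf]
    planted$condition_set_id <- sets[planted$condition_set]
    for (i in seq_len(nrow(planted))) {
      tg <- targets[[planted$tf_id[i]]]
      nc <- round(planted$fraction_coupled[i] * length(tg))
      key <- paste(planted$tf_id[i], planted$condition_set_id[i], sep = "|")
      coupled[[key]] <- sort(sample(tg, nc))
    }
  }
  structure(list(tfs = tfs, target_heads = target_heads, targets = targets,
                 condition_sets = sets, planted = planted, coupled = coupled),
            class = "sim_truth")
}

# gene ids whose promoter-centre neighbourhood [centre - margin,
# centre + margin] intersects no other gene's promoter window
.unambiguous_promoters <- function(annotation, margin,
                                   upstream = 250, downstream = 50) {
  plus <- annotation$strand == "+"
  win_lo <- ifelse(plus, annotation$start_codon - upstream,
                   annotation$start_codon - downstream)
  win_hi <- ifelse(plus, annotation$start_codon + downstream,
                   annotation$start_codon + upstream)
  centre <- ifelse(plus, annotation$start_codon - 100,
                   annotation$start_codon + 100)
  windows <- GenomicRanges::GRanges(
    annotation$replicon, IRanges::IRanges(pmax(win_lo, 1), win_hi))
  nbhd <- GenomicRanges::GRanges(
    annotation$replicon,
    IRanges::IRanges(pmax(centre - margin, 1), centre + margin))
  hits <- GenomicRanges::countOverlaps(nbhd, windows)
  annotation$gene_id[hits == 1L] # only the gene's own window
}

#' Simulate per-TF binding-site lists
#'
#' Every planted target head receives one significant site (p <= 0.01)
#' jittered around its promoter centre (100 bp upstream of the start codon,
#' the middle of the default -250/+50 window). Decoy sites (p > 0.01,
#' random positions) and significant gene-body sites are added per config to
#' exercise the p-value and window filters.
#'
#' @param config a [sim_config()].
#' @param annotation,truth outputs of [sim_annotation()] and [sim_truth()].
#' @param decoys overrides `config$decoys_per_tf` when given.
#' @return data frame with columns `tf`, `replicon`, `position`, `intensity`,
#'   `pvalue`.
#' @export
sim_binding_sites <- function(config, annotation, truth, decoys = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  decoys <- decoys %||% config$decoys_per_tf
  rl <- attr(annotation, "replicon_lengths")
  idx <- match(unlist(truth$target_heads, use.names = FALSE),
               annotation$gene_id)
  out <- list()
  for (tf in truth$tfs) {
    th <- truth$target_heads[[tf]]
    i <- match(th, annotation$gene_id)
    centre <- ifelse(annotation$strand[i] == "+",
                     annotation$start_codon[i] - 100L,
                     annotation$start_codon[i] + 100L)
    jit <- rnorm(length(th), 0, config$jitter_sd)
    jit <- pmin(pmax(jit, -3 * config$jitter_sd), 3 * config$jitter_sd)
    pos <- pmax(1L, round(centre + jit))
    planted <- data.frame(tf = tf, replicon = annotation$replicon[i],
                          position = pos,
                          intensity = runif(length(th), 1, 10),
                          pvalue = runif(length(th), 1e-6, 0.01))
    extra <- NULL
    if (decoys > 0L) {
      rp <- sample(names(rl), decoys, replace = TRUE)
      extra <- data.frame(tf = tf, replicon = rp,
                          position = sapply(rl[rp], function(L)
                            sample.int(as.integer(L), 1L)),
                          intensity = runif(decoys, 0.1, 2),
                          pvalue = runif(decoys, 0.011, 1))
    }
    genic <- NULL
    if (config$genic_decoys_per_tf > 0L) {
      gidx <- sample.int(nrow(annotation), config$genic_decoys_per_tf)
      mid <- (annotation$start[gidx] + annotation$end[gidx]) %/% 2L
      genic <- data.frame(tf = tf, replicon = annotation$replicon[gidx],
                          position = mid,
                          intensity = runif(length(gidx), 1, 5),
                          pvalue = runif(length(gidx), 1e-6, 0.01))
    }
    out[[tf]] <- rbind(planted, extra, genic)
  }
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  sites
}

#' Simulate an expression compendium with planted conditional regulons
#'
#' Arrays are grouped into condition sets. Every value starts as independent
#' Gaussian noise in log2-ratio space, and within each condition set a
#' random `responder_prob` fraction of genes additionally responds to the
#' condition along a set-specific latent profile with per-gene amplitudes
#' (emulating the many co-regulated modules of a real compendium; latent
#' profiles are independent of every TF). Within a planted (TF, set) pair the
#' TF's profile is a random permutation of an equally spaced induction ramp
#' over `[0, 2*tf_amp]` (so its fold change across the set always clears the
#' 1.75-fold filter), and each coupled target equals
#' `sign(role) * beta * TF + noise`. In unplanted sets a TF gets a set-level
#' mean shift plus array-to-array variation so the fold-change filter sees a
#' realistic mix of passing and failing sets. A `missing_rate` fraction of
#' values is set to NA.
#'
#' @param config a [sim_config()].
#' @param truth output of [sim_truth()].
#' @return an [expression compendium][new_compendium].
#' @export
sim_compendium <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 3L)
  ns <- config$n_condition_sets
  naps <- config$arrays_per_set
  n_arr <- if (naps[1L] == naps[2L]) rep(naps[1L], ns) else
    sample(naps[1L]:naps[2L], ns, replace = TRUE)
  sets <- truth$condition_sets
  array_id <- sprintf("A%03d", seq_len(sum(n_arr)))
  manifest <- data.frame(array_id = array_id,
                         condition_set_id = rep(sets, n_arr))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mat <- matrix(rnorm(length(genes) * length(array_id), 0, config$noise_sd),
                nrow = length(genes),
                dimnames = list(genes, array_id))
  cols_of_set <- split(seq_along(array_id), manifest$condition_set_id)
  # background condition response: per set, a random subset of genes moves
  # along a latent condition profile with gene-specific amplitudes
  if (config$responder_prob > 0 && config$responder_sd > 0) {
    for (s in sets) {
      cols <- cols_of_set[[s]]
      resp <- which(runif(length(genes)) < config$responder_prob)
      if (length(resp)) {
        amp <- rnorm(length(resp), 0, config$responder_sd)
        latent <- rnorm(length(cols))
        mat[resp, cols] <- mat[resp, cols] + outer(amp, latent)
      }
    }
  }
  planted_key <- character(0)
  if (!is.null(truth$planted)) {
    planted_key <- paste(truth$planted$tf_id, truth$planted$condition_set_id,
                         sep = "|")
  }
  for (tf in truth$tfs) {
    for (s in seq_along(sets)) {
      cols <- cols_of_set[[sets[s]]]
      key <- paste(tf, sets[s], sep = "|")
      pi <- match(key, planted_key)
      if (!is.na(pi)) {
        ramp <- seq(0, 2 * config$tf_amp, length.out = length(cols))
        tfvals <- sample(ramp)
        mat[tf, cols] <- tfvals
        sgn <- if (truth$planted$role[pi] == "activator") 1 else -1
        beta <- truth$planted$beta[pi]
        cg <- truth$coupled[[key]]
        cg <- setdiff(cg, tf)
        if (length(cg)) {
          mat[cg, cols] <- sgn * beta *
            matrix(tfvals, length(cg), length(cols), byrow = TRUE) +
            rnorm(length(cg) * length(cols), 0, config$noise_sd)
        }
      } else {
        delta <- rnorm(1L, 0, config$tf_shift_sd)
        mat[tf, cols] <- delta + rnorm(length(cols), 0, config$tf_profile_sd)
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- runif(length(mat)) < config$missing_rate
    mat[miss] <- NA_real_
  }
  new_compendium(mat, manifest)
}

#' Simulate growth curves from lagged logistic parameters
#'
#' OD600 holds at the inoculation density until the strain's lag time, then
#' follows a logistic towards carrying capacity `K` at rate `r`. Noise is
#' multiplicative log-normal (plate readers err proportionally), floored at
#' OD 0.01. The sampling grid is every 30 minutes for 96 hours from a
#' starting OD of 0.09, the standard high-throughput design.
#'
#' @param strain_params data frame with columns `strain`, `K`, `r`, `lag`
#'   (per-hour rate, hours of lag).
#' @param noise_sd sd of the log-normal multiplicative noise (log-OD units).
#' @param seed RNG seed.
#' @param od0 inoculation OD600.
#' @param hours,dt duration (h) and sampling interval (h).
#' @param bio_reps,tech_reps biological and technical replicates per strain.
#' @return data frame with columns `strain`, `bio_rep`, `tech_rep`, `time_h`,
#'   `od600`.
#' @export
sim_growth_curves <- function(strain_params, noise_sd = 0.02, seed = 1L,
                              od0 = 0.09, hours = 96, dt = 0.5,
                              bio_reps = 3L, tech_reps = 2L) {
  stopifnot(is.data.frame(strain_params),
            all(c("strain", "K", "r", "lag") %in% names(strain_params)))
  if (any(strain_params$K <= 0) || any(strain_params$r <= 0)) {
    stop("K and r must be positive", call. = FALSE)
  }
  set.seed(seed)
  times <- seq(0, hours, by = dt)
  out <- list()
  for (i in seq_len(nrow(strain_params))) {
    p <- strain_params[i, ]
    te <- pmax(times - p$lag, 0)
    od <- p$K * od0 / (od0 + (p$K - od0) * exp(-p$r * te))
    for (b in seq_len(bio_reps)) for (tr in seq_len(tech_reps)) {
      noisy <- pmax(od * exp(rnorm(length(od), 0, noise_sd)), 0.01)
      out[[length(out) + 1L]] <- data.frame(
        strain = p$strain, bio_rep = b, tech_rep = tr,
        time_h = times, od600 = noisy)
    }
  }
  do.call(rbind, out)
}

#' Simulate nine-residue effector-preference profiles
#'
#' Each TF inherits its group's consensus nine-residue profile with
#' `n_mutations` positions mutated to random different amino acids, for
#' testing the BLOSUM62 profile-clustering route.
#'
#' @param cluster_spec data frame with columns `tf`, `group`, `consensus`
#'   (length-9 amino-acid string) and optionally `n_mutations` (default 0).
#' @param seed RNG seed.
#' @return named character vector of length-9 profiles.
#' @export
sim_residue_profiles <- function(cluster_spec, seed = 1L) {
  stopifnot(is.data.frame(cluster_spec),
            all(c("tf", "group", "consensus") %in% names(cluster_spec)))
  aa <- .aa_alphabet()
  if (any(nchar(cluster_spec$consensus) != 9L)) {
    stop("consensus profiles must be exactly 9 residues", call. = FALSE)
  }
  letters_used <- unique(unlist(strsplit(cluster_spec$consensus, "")))
  if (!all(letters_used %in% aa)) {
    stop("consensus contains a letter outside the 20 amino-acid alphabet",
         call. = FALSE)
  }
  nm <- cluster_spec$n_mutations %||% rep(0L, nrow(cluster_spec))
  if (is.null(cluster_spec$n_mutations)) cluster_spec$n_mutations <- nm
  set.seed(seed)
  profiles <- character(nrow(cluster_spec))
  for (i in seq_len(nrow(cluster_spec))) {
    res <- strsplit(cluster_spec$consensus[i], "")[[1L]]
    m <- cluster_spec$n_mutations[i]
    if (m > 0L) {
      pos <- sample.int(9L, m)
      for (p in pos) res[p] <- sample(setdiff(aa, res[p]), 1L)
    }
    profiles[i] <- paste(res, collapse = "")
  }
  names(profiles) <- cluster_spec$tf
  profiles
}

#' Generate a full synthetic study in one call
#'
#' Convenience wrapper running [sim_annotation()], [sim_truth()],
#' [sim_binding_sites()] and [sim_compendium()] under one config.
#'
#' @param config a [sim_config()].
#' @return list with `annotation`, `truth`, `sites`, `compendium`.
#' @export
sim_study <- function(config) {
  annotation <- sim_annotation(config)
  truth <- sim_truth(config, annotation)
  sites <- sim_binding_sites(config, annotation, truth)
  compendium <- sim_compendium(config, truth)
  list(annotation = annotation, truth = truth, sites = sites,
       compendium = compendium)
}

#' Write the ground-truth sidecar for a synthetic study
#'
#' @param truth a [sim_truth()] object.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
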