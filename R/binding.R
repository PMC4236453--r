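#' Assign binding sites to target genes via promoter windows
#'
#' A gene is a direct target of a TF when a site with `pvalue <= p_max` lies
#' inside its strand-aware promoter window: for a `+` strand gene with start
#' codon at `s` the window is `[s - upstream, s + downstream]`, mirrored for
#' `-` strand genes (`[s - downstream, s + upstream]`). Sites are point
#' estimates; a site is "in" a window by its position alone, with inclusive
#' bounds. When the promoter of an operon member is hit, every member
#' further downstream in the same operon (higher `operon_rank`) becomes an
#' operon-propagated target. The defaults (p <= 0.01, -250/+50 bp) are the
#' standard promoter geometry for compact prokaryotic genomes, where the
#' mean upstream intergenic region is ~200 bp and peak calls carry ~50 bp
#' resolution.
#'
#' @param sites peak data frame (`tf`, `replicon`, `position`, `pvalue`).
#' @param annotation a `gene_annotation` data frame.
#' @param p_max peak p-value cutoff.
#' @param upstream,downstream promoter window extent in bp around the start
#'   codon, along the gene's strand.
#' @return a `target_map` data frame with columns `tf`, `gene_id`,
#'   `provenance` (`"direct-promoter"` or `"operon-propagated"`),
#'   deduplicated; direct evidence wins when both apply. Use
#'   [target_sets()] for a plain list of gene-id vectors.
#' @examples
#' ann <- sim_annotation(sim_config(n_genes = 20, n_operons = 10, seed = 1))
#' tr <- sim_truth(sim_config(n_genes = 20, n_operons = 10,
#'                            targets_per_tf = c(3, 3), seed = 1), ann)
#' sites <- sim_binding_sites(sim_config(n_genes = 20, n_operons = 10,
#'                                       seed = 1), ann, tr, decoys = 0)
#' assign_targets(sites, ann)
#' @export
assign_targets <- function(sites, annotation, p_max = 0.01,
                           upstream = 250, downstream = 50) {
  if (upstream < 0 || downstream < 0) {
    stop("window extents must be non-negative", call. = FALSE)
  }
  .assert_prob(p_max, "p_max", open_left = TRUE)
  known <- unique(annotation$replicon)
  rl <- attr(annotation, "replicon_lengths")
  if (!is.null(rl)) known <- unique(c(known, names(rl)))
  if (any(!sites$replicon %in% known)) {
    bad <- unique(sites$replicon[!sites$replicon %in% known])
    stop("binding sites on unknown replicon(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  plus <- annotation$strand == "+"
  win_lo <- ifelse(plus, annotation$start_codon - upstream,
                   annotation$start_codon - downstream)
  win_hi <- ifelse(plus, annotation$start_codon + downstream,
                   annotation$start_codon + upstream)
  windows <- GenomicRanges::GRanges(
    annotation$replicon, IRanges::IRanges(pmax(win_lo, 1L), win_hi))
  keep <- sites$pvalue <= p_max
  out <- list()
  for (tf in unique(sites$tf)) {
    s <- sites[keep & sites$tf == tf, , drop = FALSE]
    hit_genes <- character(0)
    if (nrow(s)) {
      pts <- GenomicRanges::GRanges(s$replicon,
                                    IRanges::IRanges(s$position, s$position))
      hits <- GenomicRanges::countOverlaps(windows, pts) > 0L
      hit_genes <- annotation$gene_id[hits]
    }
    prop_genes <- character(0)
    if (length(hit_genes)) {
      hit_idx <- match(hit_genes, annotation$gene_id)
      min_rank <- tapply(annotation$operon_rank[hit_idx],
                         annotation$operon_id[hit_idx], min)
      in_op <- annotation$operon_id %in% names(min_rank)
      # compare each gene's rank with the lowest hit rank in its operon
      mr <- rep(NA_real_, nrow(annotation))
      mr[in_op] <- min_rank[annotation$operon_id[in_op]]
      downstream_of_hit <- in_op & annotation$operon_rank > mr
      prop_genes <- setdiff(annotation$gene_id[downstream_of_hit], hit_genes)
    }
    if (length(hit_genes) || length(prop_genes)) {
      out[[tf]] <- data.frame(
        tf = tf,
        gene_id = c(hit_genes, prop_genes),
        provenance = rep(c("direct-promoter", "operon-propagated"),
                         c(length(hit_genes), length(prop_genes))),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(0), gene_id = character(0),
               provenance = character(0))
  rownames(res) <- NULL
  class(res) <- c("target_map", "data.frame")
  res
}

#' Extract per-TF target gene sets from a target map
#'
#' @param target_map output of [assign_targets()] (or a data frame with
#'   `tf` and `gene_id` columns).
#' @return named list of sorted gene-id vectors.
#' @export
target_sets <- function(target_map) {
  lapply(split(target_map$gene_id, target_map$tf),
         function(g) sort(unique(g)))
}

#' Genic/intergenic context of binding sites versus the genome
#'
#' Classifies each site by whether its position falls inside any annotated
#' gene body, and compares with the base-pair fraction of the genome covered
#' by gene bodies.
#'
#' @inheritParams assign_targets
#' @return list with elements `sites` and `genome`, each a named vector
#'   `c(genic = , intergenic = )` summing to 1.
#' @export
peak_context_fractions <- function(sites, annotation) {
  rl <- attr(annotation, "replicon_lengths")
  if (is.null(rl) || any(!unique(sites$replicon) %in% names(rl))) {
    stop("replicon lengths missing for some site replicons", call. = FALSE)
  }
  bodies <- GenomicRanges::reduce(GenomicRanges::GRanges(
    annotation$replicon, IRanges::IRanges(annotation$start, annotation$end)))
  genic_bp <- sum(as.numeric(GenomicRanges::width(bodies)))
  total_bp <- sum(as.numeric(rl))
  pts <- GenomicRanges::GRanges(sites$replicon,
                                IRanges::IRanges(sites$position,
                                                 sites$position))
  in_gene <- GenomicRanges::countOverlaps(pts, bodies) > 0L
  list(sites = c(genic = mean(in_gene), intergenic = mean(!in_gene)),
       genome = c(genic = genic_bp / total_bp,
                  intergenic = 1 - genic_bp / total_bp))
}

#' Overlap between two target-gene sets
#'
#' Reports the intersection size, the percent overlap relative to the
#' smaller set, and the upper-tail hypergeometric enrichment p-value
#' P(X >= k) for drawing `|B|` genes from a universe of `N` containing
#' `|A|` successes.
#'
#' @param a,b character vectors of gene ids.
#' @param universe character vector, the gene universe; both sets must be
#'   subsets of it.
#' @return list with `k`, `percent_overlap`, `pvalue`.
#' @examples
#' target_overlap(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:10))
#' @export
target_overlap <- function(a, b, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("both gene sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(a, b))
  N <- length(universe)
  p <- phyper(k - 1L, length(a), N - length(a), length(b),
              lower.tail = FALSE)
  denom <- min(length(a), length(b))
  list(k = k,
       percent_overlap = if (denom > 0) 100 * k / denom else NA_real_,
       pvalue = p)
}

#' Enrichment of genes bound by multiple TFs
#'
#' Counts genes targeted by at least `min_tfs` factors and compares the
#' count with a permutation null in which each TF's target set is redrawn
#' uniformly from the universe, preserving its size. The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (n_perm + 1)`, whose floor
#' `1/(n_perm + 1)` matches the convention of reporting `p < 1/n_perm` when
#' no null draw reaches the observed count.
#'
#' @param target_maps named list of gene-id vectors (or a `target_map`).
#' @param universe gene universe.
#' @param min_tfs minimum number of binding TFs (>= 2).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed` and `pvalue`.
#' @export
multi_binding_enrichment <- function(target_maps, universe, min_tfs = 2L,
                                     n_perm = 10000L, seed = 1L) {
  if (inherits(target_maps, "target_map")) {
    target_maps <- target_sets(target_maps)
  }
  min_tfs <- .assert_scalar_count(min_tfs, "min_tfs")
  if (min_tfs < 2L) stop("min_tfs must be >= 2", call. = FALSE)
  universe <- unique(universe)
  N <- length(universe)
  sizes <- lengths(target_maps)
  if (any(sizes > N)) {
    stop("a target set is larger than the universe", call. = FALSE)
  }
  counts <- table(factor(unlist(lapply(target_maps, unique),
                                use.names = FALSE), levels = universe))
  observed <- sum(counts >= min_tfs)
  set.seed(seed)
  null_ge <- 0L
  for (i in seq_len(n_perm)) {
    cnt <- integer(N)
    for (k in sizes) {
      j <- sample.int(N, k)
      cnt[j] <- cnt[j] + 1L
    }
    if (sum(cnt >= min_tfs) >= observed) null_ge <- null_ge + 1L
  }
  list(observed = observed, pvalue = (1 + null_ge) / (n_perm + 1))
}
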