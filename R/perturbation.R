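# Deletion-strain validation of predicted conditional regulation:
# per-gene expression contrasts between two defined samples, replicate
# medians, and a one-sided rank-sum comparison of mutant vs control.

#' Per-gene expression change between two samples
#'
#' `delta = expr[, sample_a] - expr[, sample_b]`, restricted to `gene_set`.
#' For relative activation `sample_a` is the early (pre-shutdown) sample
#' and `sample_b` the late one; for relative repression `sample_a` is the
#' high-density sample and `sample_b` the starting one. Genes missing a
#' value in either sample are dropped with a message.
#'
#' @param expr numeric matrix of log2 expression, genes x arrays.
#' @param gene_set character vector of gene ids.
#' @param sample_a,sample_b array (column) ids.
#' @return named numeric vector of deltas (log2 units).
#' @export
relative_change <- function(expr, gene_set, sample_a, sample_b) {
  if (identical(sample_a, sample_b)) {
    stop("sample_a and sample_b must differ", call. = FALSE)
  }
  genes <- intersect(gene_set, rownames(expr))
  d <- expr[genes, sample_a] - expr[genes, sample_b]
  drop <- !is.finite(d)
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped for missing values")
    d <- d[!drop]
  }
  d
}

#' One-sided rank-sum comparison of mutant vs control replicate statistics
#'
#' Unpaired Wilcoxon rank-sum test between the two groups of replicate
#' summary statistics (typically the per-replicate median delta over the
#' selected gene set). Exact for group sizes up to 8 without ties, normal
#' approximation (with continuity correction) otherwise. For biological
#' triplicates the smallest attainable one-sided p is 1/C(6,3) = 0.05.
#'
#' @param deltas_mutant,deltas_control numeric vectors of replicate
#'   statistics.
#' @param alternative `"less"` (mutant below control, activation deficit),
#'   `"greater"` (repression deficit) or `"two.sided"`.
#' @return the p-value.
#' @export
strain_effect_test <- function(deltas_mutant, deltas_control,
                               alternative = c("less", "greater",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(deltas_mutant) || !length(deltas_control)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  nx <- length(deltas_mutant); ny <- length(deltas_control)
  ties <- anyDuplicated(c(deltas_mutant, deltas_control)) > 0L
  exact <- nx <= 8L && ny <= 8L && !ties
  suppressWarnings(
    wilcox.test(deltas_mutant, deltas_control, alternative = alternative,
                exact = exact)$p.value)
}

#' Validate a predicted conditional regulon against deletion-strain arrays
#'
#' For each biological replicate of each strain, computes the per-gene
#' delta between the two design samples and reduces it to the median over
#' the selected gene set; then compares mutant vs control replicate medians
#' with a one-sided rank-sum test. The direction follows the predicted
#' role: an activator's mutant should show *less* activation than control
#' (`"less"`); a repressor's mutant should show *less* repression, i.e.
#' larger deltas (`"greater"`).
#'
#' @param expr numeric matrix of log2 expression, genes x arrays.
#' @param gene_set selected conditional-regulon genes.
#' @param design data frame with columns `strain`, `bio_rep`, `sample`
#'   (label), `array_id`.
#' @param mutant,control strain identifiers in `design`.
#' @param sample_a,sample_b the two sample labels contrasted
#'   (delta = a - b).
#' @param direction `"activation"` or `"repression"`.
#' @return list with per-strain replicate medians and the one-sided
#'   p-value.
#' @export
perturbation_test <- function(expr, gene_set, design, mutant, control,
                              sample_a, sample_b,
                              direction = c("activation", "repression")) {
  direction <- match.arg(direction)
  stopifnot(all(c("strain", "bio_rep", "sample", "array_id") %in%
                  names(design)))
  med_of <- function(strain) {
    d <- design[design$strain == strain, , drop = FALSE]
    reps <- sort(unique(d$bio_rep))
    vapply(reps, function(b) {
      aa <- d$array_id[d$bio_rep == b & d$sample == sample_a]
      bb <- d$array_id[d$bio_rep == b & d$sample == sample_b]
      if (length(aa) != 1L || length(bb) != 1L) {
        stop(sprintf("strain %s rep %s needs exactly one array per sample",
                     strain, b), call. = FALSE)
      }
      median(relative_change(expr, gene_set, aa, bb))
    }, numeric(1))
  }
  m <- med_of(mutant); ctl <- med_of(control)
  alt <- if (direction == "activation") "less" else "greater"
  list(mutant_medians = m, control_medians = ctl,
       pvalue = strain_effect_test(m, ctl, alt))
}

#' Overlap between two conditional regulons
#'
#' Delegates to [target_overlap()]: intersection size, percent overlap
#' relative to the smaller regulon, and upper-tail hypergeometric p.
#'
#' @inheritParams target_overlap
#' @export
regulon_overlap_test <- function(a, b, universe) {
  target_overlap(a, b, universe)
}
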