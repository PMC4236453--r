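# The headline procedure: detect (TF, condition set) pairs where a factor
# conditionally activates or represses its binding targets, via the median
# TF-target correlation statistic and a permutation null of random gene
# sets of the same size.

#' Condition sets where a TF's expression changes appreciably
#'
#' A set passes when the TF's log2 expression range across the set's arrays
#' (max - min) reaches `log2(min_fold)`. Fold changes are computed in log2
#' space throughout; 1.75-fold therefore corresponds to a log2 range of
#' ~0.807. Sets where the TF is entirely missing are excluded with a
#' warning.
#'
#' @param comp an `expr_compendium`.
#' @param tf TF gene id.
#' @param min_fold minimum fold change (linear scale).
#' @return character vector of passing condition-set ids; the per-set log2
#'   range is attached as attribute `fold_change` (named, all sets).
#' @export
filter_condition_sets <- function(comp, tf, min_fold = 1.75) {
  prof <- .tf_profile(comp, tf)
  rng <- vapply(comp$sets, function(arr) {
    v <- prof[arr]
    if (all(is.na(v))) NA_real_ else
      max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(rng)) {
    warning(sprintf("TF %s has no measurements in set(s) %s; excluded", tf,
                    paste(names(rng)[is.na(rng)], collapse = ", ")),
            call. = FALSE)
  }
  pass <- names(rng)[!is.na(rng) & rng >= log2(min_fold)]
  attr(pass, "fold_change") <- rng
  pass
}

#' Correlation of each target gene with its TF within one condition set
#'
#' Correlations (Spearman by default, pairwise-complete) between the TF's
#' expression profile and each target's profile over the arrays of one
#' condition set. Targets absent from the matrix are skipped with a
#' warning; genes with fewer than 3 complete pairs give NA.
#'
#' @inheritParams filter_condition_sets
#' @param targets character vector of target gene ids.
#' @param condition_set condition-set id.
#' @param method correlation type.
#' @param min_arrays minimum arrays in the set with non-missing TF values.
#' @return named numeric vector of correlations (one per target found).
#' @export
per_gene_correlations <- function(comp, tf, targets, condition_set,
                                  method = c("spearman", "pearson"),
                                  min_arrays = 6L) {
  method <- match.arg(method)
  m <- .set_matrix(comp, condition_set)
  tf_vals <- m[tf, ]
  if (sum(!is.na(tf_vals)) < min_arrays) {
    stop(sprintf("TF %s has fewer than %d measured arrays in %s",
                 tf, min_arrays, condition_set), call. = FALSE)
  }
  found <- intersect(targets, rownames(m))
  if (length(found) < length(targets)) {
    warning(sprintf("%d target(s) absent from matrix; skipped",
                    length(targets) - length(found)), call. = FALSE)
  }
  .row_correlations(m[found, , drop = FALSE], tf_vals, method)
}

#' Median correlation statistic
#'
#' The median over all finite target correlations; its sign proposes the
#' role (positive: activator, negative: repressor). Both tails are tested
#' downstream regardless of the sign.
#'
#' @param per_gene_r numeric vector of per-target correlations.
#' @return the median (scalar).
#' @export
median_statistic <- function(per_gene_r) {
  r <- per_gene_r[is.finite(per_gene_r)]
  if (!length(r)) stop("no finite correlations; statistic undefined",
                       call. = FALSE)
  median(r)
}

#' Permutation p-value for a median correlation statistic
#'
#' Draws `n_perm` random gene sets of the observed size (without
#' replacement from all genes on the array, the tested TF excluded),
#' computes each draw's median correlation with the TF inside the condition
#' set, and returns the add-one estimator
#' `p = (1 + #{draws as-or-more-extreme}) / (n_perm + 1)`. With the default
#' 100,000 permutations the estimator's floor is `1/100001 < 1e-5`, the
#' conventional reporting floor. The per-gene correlation vector is
#' computed once; each draw is just a median of sampled entries.
#'
#' @inheritParams per_gene_correlations
#' @param set_size number of genes per random draw.
#' @param observed_median observed median correlation.
#' @param tail `"upper"` (activator) or `"lower"` (repressor).
#' @param n_perm number of random gene sets.
#' @param seed RNG seed.
#' @return the p-value, with the null medians as attribute `null`.
#' @export
permutation_pvalue <- function(comp, tf, set_size, condition_set,
                               observed_median,
                               tail = c("upper", "lower"),
                               n_perm = 100000L, seed = 1L,
                               method = c("spearman", "pearson")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  set_size <- .assert_scalar_count(set_size, "set_size")
  m <- .set_matrix(comp, condition_set)
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  tf_vals <- m[tf, ]
  if (set_size > nrow(m) - 1L) {
    stop("set_size exceeds the gene universe (TF excluded)", call. = FALSE)
  }
  r_all <- .row_correlations(m, tf_vals, method)
  set.seed(seed)
  nul <- perm_null_stats(r_all, matrix(numeric(0), 0, 0), tf_vals,
                         set_size, n_perm, FALSE,
                         match(tf, rownames(m)) - 1L)$median
  p <- .tail_pvalue(nul, observed_median, tail)
  attr(p, "null") <- nul
  p
}

.tail_pvalue <- function(null_values, observed, tail) {
  ok <- is.finite(null_values)
  n <- sum(ok)
  extreme <- if (tail == "upper") sum(null_values[ok] >= observed) else
    sum(null_values[ok] <= observed)
  (1 + extreme) / (n + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, `q_(i) = min_(j>=i) m p_(j) / j` capped at 1,
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  .assert_prob(pvalues[!is.na(pvalues)], "pvalues", open_left = TRUE)
  p.adjust(pvalues, method = "BH")
}

#' Dispersion-coupling filter
#'
#' Tests whether the spread of a TF's targets tracks the TF's own
#' expression within a condition set: the per-array dispersion is the
#' variance across target genes at each array, the statistic is the
#' absolute Spearman correlation between that dispersion series and the
#' TF profile, and the p-value comes from the same random-gene-set
#' permutation machinery as the median statistic. Degenerate target sets
#' (constant across arrays, undefined correlation) fail closed with a
#' warning.
#'
#' @inheritParams per_gene_correlations
#' @param n_perm,seed permutation settings.
#' @return list with `statistic` and `pvalue` (both NA when degenerate).
#' @export
dispersion_coupling_filter <- function(comp, tf, targets, condition_set,
                                       n_perm = 100000L, seed = 1L) {
  m <- .set_matrix(comp, condition_set)
  if (ncol(m) < 3L) {
    warning("fewer than 3 arrays; dispersion filter skipped", call. = FALSE)
    return(list(statistic = NA_real_, pvalue = NA_real_))
  }
  tf_vals <- m[tf, ]
  found <- intersect(targets, rownames(m))
  obs <- .dispersion_stat(m[found, , drop = FALSE], tf_vals)
  if (!is.finite(obs)) {
    warning("dispersion statistic undefined (constant targets?); ",
            "filter fails closed", call. = FALSE)
    return(list(statistic = NA_real_, pvalue = NA_real_))
  }
  r_dummy <- rep(0, nrow(m))
  set.seed(seed)
  nul <- perm_null_stats(r_dummy, t(m), tf_vals, length(found), n_perm,
                         TRUE, match(tf, rownames(m)) - 1L)$dispersion
  list(statistic = obs, pvalue = .tail_pvalue(nul, obs, "upper"))
}

# |Spearman| between per-array cross-gene variance and the TF profile
.dispersion_stat <- function(target_mat, tf_vals) {
  v <- apply(target_mat, 2L, function(col) {
    col <- col[is.finite(col)]
    if (length(col) >= 2L) var(col) else NA_real_
  })
  ok <- is.finite(v) & is.finite(tf_vals)
  if (sum(ok) < 3L) return(NA_real_)
  suppressWarnings(abs(cor(v[ok], tf_vals[ok], method = "spearman")))
}

#' Select the conditionally regulated gene subset
#'
#' Activator regulons keep targets whose correlation exceeds the median of
#' all target correlations; repressor regulons keep those below it
#' (strict inequalities, so with all-equal correlations nothing is
#' selected and with distinct values exactly `floor(n/2)` genes are).
#'
#' @param per_gene_r named numeric vector of target correlations.
#' @param role `"activator"` or `"repressor"`.
#' @return character vector of selected gene ids.
#' @export
select_conditional_genes <- function(per_gene_r,
                                     role = c("activator", "repressor")) {
  role <- match.arg(role)
  r <- per_gene_r[is.finite(per_gene_r)]
  if (!length(r)) return(character(0))
  med <- median(r)
  keep <- if (role == "activator") r > med else r < med
  names(r)[keep]
}

#' Call conditional regulons across all TFs and condition sets
#'
#' The full procedure: (1) keep condition sets where the TF moves at least
#' `min_fold` (log2 range); (2) correlate the TF with each of its binding
#' targets inside each passing set; (3) take the median correlation;
#' (4) compare it with random gene sets of the same size in both tails
#' (activator and repressor); (5) adjust all TF x set x tail permutation
#' p-values jointly by Benjamini-Hochberg; (6) require the targets'
#' per-array dispersion to be coupled to the TF (its own permutation test,
#' BH-adjusted across TF x set pairs); (7) report a call when
#' `bh_q <= alpha`, `|median_r| >= min_abs_r`, the median's sign matches
#' the tail, and the dispersion filter passes; (8) select the
#' above-median-correlated gene subset for every call.
#'
#' @param comp an `expr_compendium`.
#' @param target_maps named list of target gene-id vectors (one per TF,
#'   names are TF gene ids present in the matrix), or a `target_map` data
#'   frame from [assign_targets()].
#' @param n_perm permutations per test (default 100,000).
#' @param seed integer seed; the full result is reproducible given
#'   identical inputs and seed.
#' @param min_fold fold-change filter (linear scale).
#' @param min_abs_r minimum |median correlation| for a call.
#' @param alpha BH threshold for both the median and dispersion tests.
#' @param method correlation type within condition sets.
#' @param min_arrays minimum arrays with non-missing TF values per set;
#'   smaller sets are excluded with a warning.
#' @param dispersion_filter apply the dispersion-coupling filter (step 6)?
#' @return data frame (class `regulon_calls`) with one row per
#'   (tf, condition_set, tail): `tf`, `condition_set`, `role`,
#'   `fold_change`, `n_arrays`, `n_targets`, `median_r`, `permuted_p`,
#'   `bh_q`, `dispersion_stat`, `dispersion_p`, `dispersion_q`, `called`,
#'   `n_selected`. Selected gene sets for every called row are in
#'   `attr(, "selected")`, keyed `"tf|set|role"`.
#' @export
call_regulons <- function(comp, target_maps, n_perm = 100000L, seed = 1L,
                          min_fold = 1.75, min_abs_r = 0.4, alpha = 0.05,
                          method = c("spearman", "pearson"),
                          min_arrays = 6L, dispersion_filter = TRUE) {
  method <- match.arg(method)
  if (inherits(target_maps, "target_map")) {
    target_maps <- target_sets(target_maps)
  }
  stopifnot(is.list(target_maps), !is.null(names(target_maps)))
  # canonical orders so results are invariant to input row/column order
  tfs <- sort(names(target_maps))
  missing_tfs <- setdiff(tfs, rownames(comp$exprs))
  if (length(missing_tfs)) {
    stop("TF(s) absent from matrix: ", paste(missing_tfs, collapse = ", "),
         call. = FALSE)
  }
  genes <- rownames(comp$exprs)
  set.seed(seed)
  rows <- list()
  selected <- list()
  per_r_cache <- list()
  pass_by_tf <- lapply(setNames(tfs, tfs), function(tf)
    suppressWarnings(filter_condition_sets(comp, tf, min_fold)))
  targets_by_tf <- lapply(setNames(tfs, tfs), function(tf)
    sort(setdiff(intersect(target_maps[[tf]], genes), tf)))
  for (cs in sort(unique(unlist(pass_by_tf, use.names = FALSE)))) {
    m <- .set_matrix(comp, cs)
    m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
    # per-set caches shared across TFs: transposed slice for the
    # permutation kernel, rank transform for Spearman
    tx <- t(m)
    ranks_t <- if (method == "spearman")
      apply(m, 1L, rank, na.last = "keep") else tx
    nonmiss <- !is.na(ranks_t)
    for (tf in tfs) {
      if (!cs %in% pass_by_tf[[tf]]) next
      targets <- targets_by_tf[[tf]]
      if (!length(targets)) next
      tf_vals <- m[tf, ]
      if (sum(!is.na(tf_vals)) < min_arrays) {
        warning(sprintf("%s x %s: fewer than %d arrays with TF values; %s",
                        tf, cs, min_arrays, "excluded"), call. = FALSE)
        next
      }
      tf_stat <- if (method == "spearman")
        rank(tf_vals, na.last = "keep") else tf_vals
      r_full <- suppressWarnings(
        as.vector(cor(ranks_t, tf_stat, use = "pairwise.complete.obs")))
      r_full[colSums(nonmiss & !is.na(tf_stat)) < 3L] <- NA_real_
      names(r_full) <- rownames(m)
      r_tg <- r_full[targets]
      if (!any(is.finite(r_tg))) next
      med <- median_statistic(r_tg)
      ex <- match(tf, rownames(m)) - 1L
      nul <- perm_null_stats(r_full, tx, tf_vals, length(targets), n_perm,
                             dispersion_filter, ex)
      p_up <- .tail_pvalue(nul$median, med, "upper")
      p_lo <- .tail_pvalue(nul$median, med, "lower")
      if (dispersion_filter) {
        d_obs <- .dispersion_stat(m[targets, , drop = FALSE], tf_vals)
        d_p <- if (is.finite(d_obs))
          .tail_pvalue(nul$dispersion, d_obs, "upper") else NA_real_
      } else {
        d_obs <- d_p <- NA_real_
      }
      key <- paste(tf, cs, sep = "|")
      per_r_cache[[key]] <- r_tg
      fc <- attr(pass_by_tf[[tf]], "fold_change")
      for (tail in c("upper", "lower")) {
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, condition_set = cs,
          role = if (tail == "upper") "activator" else "repressor",
          fold_change = unname(fc[cs]),
          n_arrays = ncol(m), n_targets = length(targets),
          median_r = med,
          permuted_p = if (tail == "upper") p_up else p_lo,
          dispersion_stat = d_obs, dispersion_p = d_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    res <- data.frame(tf = character(0), condition_set = character(0),
                      role = character(0), fold_change = numeric(0),
                      n_arrays = integer(0), n_targets = integer(0),
                      median_r = numeric(0), permuted_p = numeric(0),
                      bh_q = numeric(0), dispersion_stat = numeric(0),
                      dispersion_p = numeric(0), dispersion_q = numeric(0),
                      called = logical(0), n_selected = integer(0))
    class(res) <- c("regulon_calls", "data.frame")
    attr(res, "selected") <- list()
    return(res)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$tf, res$condition_set, res$role), , drop = FALSE]
  res$bh_q <- bh_adjust(res$permuted_p)
  # one dispersion test per (tf, set) pair; adjust over pairs, then map back
  pair_key <- paste(res$tf, res$condition_set, sep = "|")
  first <- !duplicated(pair_key)
  d_q <- rep(NA_real_, sum(first))
  dp <- res$dispersion_p[first]
  d_q[!is.na(dp)] <- bh_adjust(dp[!is.na(dp)])
  res$dispersion_q <- d_q[match(pair_key, pair_key[first])]
  sign_ok <- ifelse(res$role == "activator", res$median_r > 0,
                    res$median_r < 0)
  disp_ok <- if (dispersion_filter) {
    !is.na(res$dispersion_q) & res$dispersion_q <= alpha
  } else TRUE
  res$called <- res$bh_q <= alpha & abs(res$median_r) >= min_abs_r &
    sign_ok & disp_ok
  res$n_selected <- 0L
  for (i in which(res$called)) {
    key <- paste(res$tf[i], res$condition_set[i], sep = "|")
    sel <- select_conditional_genes(per_r_cache[[key]], res$role[i])
    selected[[paste(key, res$role[i], sep = "|")]] <- sel
    res$n_selected[i] <- length(sel)
  }
  rownames(res) <- NULL
  class(res) <- c("regulon_calls", "data.frame")
  attr(res, "selected") <- selected
  attr(res, "seed") <- seed
  attr(res, "n_perm") <- n_perm
  res
}

#' @export
print.regulon_calls <- function(x, ...) {
  cat(sprintf("conditional regulon scan: %d TF x set x tail tests, %d call(s)\n",
              nrow(x), sum(x$called)))
  if (any(x$called)) {
    print.data.frame(x[x$called,
                       c("tf", "condition_set", "role", "median_r",
                         "permuted_p", "bh_q", "n_selected")],
                     row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write regulon calls and per-call gene lists
#'
#' @param calls a `regulon_calls` data frame.
#' @param path results TSV path.
#' @param genes_dir optional directory for per-call gene lists (one text
#'   file per call).
#' @export
write_regulon_calls <- function(calls, path, genes_dir = NULL) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(genes_dir)) {
    dir.create(genes_dir, showWarnings = FALSE, recursive = TRUE)
    sel <- attr(calls, "selected")
    for (key in names(sel)) {
      fn <- file.path(genes_dir, paste0(gsub("[|]", "_", key), ".txt"))
      writeLines(sel[[key]], fn)
    }
  }
  invisible(path)
}
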