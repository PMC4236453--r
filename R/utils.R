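# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  }
  as.integer(x)
}

.assert_prob <- function(x, name, open_left = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x > 1) ||
      any(if (open_left) x <= 0 else x < 0)) {
    stop(sprintf("'%s' must lie in %s", name,
                 if (open_left) "(0, 1]" else "[0, 1]"), call. = FALSE)
  }
  x
}

# Spearman/Pearson correlation of every row of `m` (genes x arrays) with the
# vector `y` (length ncol(m)), pairwise-complete. Rows with fewer than
# `min_pairs` complete pairs give NA. For Spearman, values are rank
# transformed once per vector (NAs kept), then correlated pairwise.
.row_correlations <- function(m, y, method = c("spearman", "pearson"),
                              min_pairs = 3L) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), length(y) == ncol(m))
  if (method == "spearman") {
    m <- t(apply(m, 1L, rank, na.last = "keep"))
    y <- rank(y, na.last = "keep")
  }
  r <- suppressWarnings(as.vector(cor(t(m), y, use = "pairwise.complete.obs")))
  pairs <- as.vector((!is.na(m)) %*% (!is.na(y)))
  r[pairs < min_pairs] <- NA_real_
  names(r) <- rownames(m)
  r
}

# Two-sided / one-sided p-value for a correlation coefficient: exact
# permutation via cor.test for small n without ties, t approximation
# otherwise.
.cor_pvalue <- function(x, y, method = "spearman") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  exact <- method == "spearman" && n < 10L &&
    !anyDuplicated(x) && !anyDuplicated(y)
  suppressWarnings(
    cor.test(x, y, method = method, exact = exact)$p.value
  )
}
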