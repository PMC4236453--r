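#' Construct an expression compendium
#'
#' A compendium is a genes x arrays matrix of log2 expression ratios plus a
#' manifest grouping arrays into named environmental condition sets. Every
#' array in the matrix must appear in the manifest and every condition set
#' must contain at least two arrays.
#'
#' @param mat numeric matrix, rows named by gene id, columns by array id.
#' @param manifest data frame with columns `array_id`, `condition_set_id`.
#' @return object of class `expr_compendium`: list with `exprs`, `manifest`
#'   and `sets` (named list of array-id vectors).
#' @export
new_compendium <- function(mat, manifest) {
  stopifnot(is.matrix(mat), is.data.frame(manifest),
            all(c("array_id", "condition_set_id") %in% names(manifest)))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix needs gene row names and array column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "), call. = FALSE)
  }
  missing_arrays <- setdiff(colnames(mat), manifest$array_id)
  if (length(missing_arrays)) {
    stop("array(s) missing from manifest: ",
         paste(missing_arrays, collapse = ", "), call. = FALSE)
  }
  manifest <- manifest[match(colnames(mat), manifest$array_id), , drop = FALSE]
  sets <- split(manifest$array_id, manifest$condition_set_id)
  small <- names(sets)[lengths(sets) < 2L]
  if (length(small)) {
    stop("condition set(s) with fewer than 2 arrays: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  structure(list(exprs = mat, manifest = manifest, sets = sets),
            class = "expr_compendium")
}

#' @export
print.expr_compendium <- function(x, ...) {
  cat(sprintf(
    "expression compendium: %d genes x %d arrays in %d condition sets\n",
    nrow(x$exprs), ncol(x$exprs), length(x$sets)))
  cat(sprintf("missing values: %.2f%%\n", 100 * mean(is.na(x$exprs))))
  invisible(x)
}

#' Load an expression compendium from TSV files
#'
#' @param matrix_path TSV of log2 ratios, first column gene ids, remaining
#'   columns named by array id.
#' @param manifest_path TSV with columns `array_id`, `condition_set_id`.
#' @return an `expr_compendium`; per-gene missing-value rates are attached
#'   as attribute `missing_rate`.
#' @export
load_compendium <- function(matrix_path, manifest_path) {
  raw <- read.delim(matrix_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s) in matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- genes
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  comp <- new_compendium(mat, manifest)
  attr(comp, "missing_rate") <- rowMeans(is.na(mat))
  comp
}

#' Write a compendium to TSV files
#'
#' @param comp an `expr_compendium`.
#' @inheritParams load_compendium
#' @export
write_compendium <- function(comp, matrix_path, manifest_path) {
  df <- data.frame(gene_id = rownames(comp$exprs), comp$exprs,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(comp$manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

.set_matrix <- function(comp, condition_set) {
  arrays <- comp$sets[[condition_set]]
  if (is.null(arrays)) {
    stop("unknown condition set: ", condition_set, call. = FALSE)
  }
  comp$exprs[, arrays, drop = FALSE]
}

.tf_profile <- function(comp, tf) {
  if (!tf %in% rownames(comp$exprs)) {
    stop("TF not present in expression matrix: ", tf, call. = FALSE)
  }
  comp$exprs[tf, ]
}

#' Pairwise TF co-expression across the pooled compendium
#'
#' Spearman rank correlation of every TF pair over all arrays
#' (pairwise-complete). An edge is significant when `rho >= rho_min` and
#' `p <= p_max` (signed rho: anti-correlation never makes an edge). Pairs
#' with fewer than `min_arrays` complete observations yield no edge and a
#' warning.
#'
#' @param comp an `expr_compendium`.
#' @param tfs character vector of TF gene ids (rows of the matrix).
#' @param rho_min,p_max significance cutoffs.
#' @param min_arrays minimum complete observations per pair.
#' @return data frame `tf_a`, `tf_b`, `n`, `rho`, `pvalue`, `significant`,
#'   one row per unordered pair.
#' @export
ffrp_coexpression <- function(comp, tfs, rho_min = 0.5, p_max = 0.05,
                              min_arrays = 10L) {
  missing_tfs <- setdiff(tfs, rownames(comp$exprs))
  if (length(missing_tfs)) {
    stop("TF(s) absent from matrix: ", paste(missing_tfs, collapse = ", "),
         call. = FALSE)
  }
  pairs <- combn(tfs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    x <- comp$exprs[a, ]; y <- comp$exprs[b, ]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_arrays) {
      warning(sprintf("pair %s-%s has only %d complete arrays; no edge",
                      a, b, n), call. = FALSE)
      return(data.frame(tf_a = a, tf_b = b, n = n, rho = NA_real_,
                        pvalue = NA_real_, significant = FALSE))
    }
    rho <- cor(x[ok], y[ok], method = "spearman")
    p <- .cor_pvalue(x[ok], y[ok], "spearman")
    data.frame(tf_a = a, tf_b = b, n = n, rho = rho, pvalue = p,
               significant = isTRUE(rho >= rho_min && p <= p_max))
  })
  do.call(rbind, rows)
}
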