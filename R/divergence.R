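# Type-I functional divergence distances and effector-residue clustering.
# Theta estimation itself (maximum-likelihood, from aligned homolog
# clusters) is upstream of this package: users supply a pairwise theta
# table and the package handles the transform, clustering and reporting.

#' Read a pairwise type-I functional divergence table
#'
#' Long-format TSV with columns `tf_a`, `tf_b`, `theta` and optionally `se`
#' and `pvalue`, one row per unordered pair.
#'
#' @param path TSV path.
#' @return symmetric theta matrix (class `theta_matrix`) with zero diagonal
#'   and `se`/`pvalue` matrices as attributes.
#' @export
read_theta <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf_a", "tf_b", "theta") %in% names(x)))
  tfs <- sort(unique(c(x$tf_a, x$tf_b)))
  m <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  se <- pv <- matrix(NA_real_, length(tfs), length(tfs),
                     dimnames = list(tfs, tfs))
  ia <- match(x$tf_a, tfs); ib <- match(x$tf_b, tfs)
  m[cbind(ia, ib)] <- m[cbind(ib, ia)] <- x$theta
  if (!is.null(x$se)) se[cbind(ia, ib)] <- se[cbind(ib, ia)] <- x$se
  if (!is.null(x$pvalue)) pv[cbind(ia, ib)] <- pv[cbind(ib, ia)] <- x$pvalue
  structure(m, se = se, pvalue = pv, class = c("theta_matrix", "matrix"))
}

#' The FFRP pairwise divergence table shipped with the package
#'
#' Published pairwise type-I functional divergence coefficients (with
#' standard errors and chi-square p-values) for the eight full-length FFRPs
#' of *Halobacterium salinarum* NRC-1, estimated from full-length protein
#' alignments. Shipped as the package's reference input for the divergence
#' clustering route.
#'
#' @return a `theta_matrix` (see [read_theta()]).
#' @export
ffrp_theta <- function() {
  read_theta(system.file("extdata", "ffrp_theta.tsv",
                         package = "condregulon", mustWork = TRUE))
}

#' Convert type-I divergence coefficients to functional distances
#'
#' `d = -ln(1 - theta)`: zero divergence maps to zero distance and the
#' distance grows without bound as theta approaches 1, mirroring the
#' log-transform used for evolutionary distances. The inverse transform
#' `1 - exp(-d)` recovers theta exactly.
#'
#' @param theta symmetric matrix (or `theta_matrix`) of coefficients in
#'   `[0, 1)`.
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' theta_to_distance(ffrp_theta())["AsnC", "Trh2"] # -ln(1 - 0.47)
#' @export
theta_to_distance <- function(theta) {
  m <- unclass(theta)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  if (any(!is.finite(m)) || any(m < 0) || any(m >= 1)) {
    stop("theta values must lie in [0, 1)", call. = FALSE)
  }
  d <- -log(1 - m)
  diag(d) <- 0
  d
}

#' Agglomerative clustering of a divergence distance matrix
#'
#' Thin wrapper over [stats::hclust()] restricted to the two linkages used
#' for divergence and effector trees: complete linkage for the functional
#' distance trees and average linkage (UPGMA) for effector-preference
#' clusters.
#'
#' @param dist_matrix square symmetric non-negative matrix, or a
#'   [stats::dist] object.
#' @param linkage `"complete"` or `"average"`.
#' @return an [stats::hclust] tree.
#' @export
cluster_divergence <- function(dist_matrix, linkage = c("complete",
                                                        "average")) {
  linkage <- match.arg(linkage)
  if (!inherits(dist_matrix, "dist")) {
    m <- as.matrix(dist_matrix)
    if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
      stop("distance matrix must be square and symmetric", call. = FALSE)
    }
    if (any(m < 0)) stop("distances must be non-negative", call. = FALSE)
    dist_matrix <- stats::as.dist(m)
  }
  stats::hclust(dist_matrix, method = linkage)
}

#' Export a clustering tree as a Newick string
#'
#' @param hc an [stats::hclust] tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

.aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Score nine-residue effector profiles with BLOSUM62
#'
#' The similarity between two profiles is the sum of BLOSUM62 substitution
#' scores over the nine aligned positions. Similarities are turned into
#' distances as `d_ij = (S_ii + S_jj)/2 - S_ij`, which is zero iff the two
#' profiles are score-identical and grows with substitution cost. Gap
#' characters (`-`) score as the minimum of the partner residue's BLOSUM62
#' row by default (a conservative penalty).
#'
#' @param profiles named character vector of length-9 amino-acid strings,
#'   or a data frame with columns `tf` and `residues`.
#' @param matrix substitution matrix (defaults to BLOSUM62 as shipped with
#'   Biostrings).
#' @param gap_score `"min"` (default) or a fixed numeric gap score.
#' @return list with symmetric `similarity` and `distance` matrices.
#' @examples
#' residue_similarity(c(x = "AAAAAAAAA", y = "GGGGGGGGG"))$distance
#' @export
residue_similarity <- function(profiles, matrix = NULL, gap_score = "min") {
  if (is.data.frame(profiles)) {
    profiles <- setNames(profiles$residues, profiles$tf)
  }
  if (any(nchar(profiles) != 9L)) {
    stop("all residue profiles must have exactly 9 positions", call. = FALSE)
  }
  B <- matrix %||% .blosum62()
  aa_known <- rownames(B)
  chars <- strsplit(profiles, "")
  bad <- setdiff(unique(unlist(chars)), c(aa_known, "-"))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  score_pair <- function(a, b) {
    s <- 0
    for (k in seq_len(9L)) {
      x <- a[k]; y <- b[k]
      if (x == "-" || y == "-") {
        other <- if (x == "-") y else x
        s <- s + if (other == "-") 0 else if (identical(gap_score, "min"))
          min(B[other, ]) else gap_score
      } else {
        s <- s + B[x, y]
      }
    }
    s
  }
  n <- length(profiles)
  S <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n)) for (j in i:n) {
    S[i, j] <- S[j, i] <- score_pair(chars[[i]], chars[[j]])
  }
  D <- (outer(diag(S), diag(S), `+`)) / 2 - S
  list(similarity = S, distance = D)
}

#' Cluster TFs by effector-preference residue profiles
#'
#' Average-linkage clustering of the BLOSUM62 profile distance
#' (see [residue_similarity()]), cut either into `k` groups or at height
#' `h`. Each cluster is annotated with its positional consensus residues
#' (most frequent letter per position, ties to the alphabetically first).
#'
#' @inheritParams residue_similarity
#' @param k number of clusters, or `NULL` to cut by height.
#' @param h dendrogram cut height (used when `k` is `NULL`).
#' @return data frame `tf`, `cluster` with a `consensus` attribute (named
#'   character vector of per-cluster consensus profiles) and the `hclust`
#'   tree as attribute `tree`.
#' @export
effector_clusters <- function(profiles, k = NULL, h = NULL,
                              matrix = NULL, gap_score = "min") {
  if (is.data.frame(profiles)) {
    profiles <- setNames(profiles$residues, profiles$tf)
  }
  rs <- residue_similarity(profiles, matrix = matrix, gap_score = gap_score)
  hc <- cluster_divergence(rs$distance, "average")
  if (is.null(k) && is.null(h)) h <- mean(hc$height)
  cl <- if (!is.null(k)) stats::cutree(hc, k = k) else
    stats::cutree(hc, h = h)
  if (!length(unique(cl))) stop("cutoff yields no clusters", call. = FALSE)
  consensus <- vapply(split(names(cl), cl), function(tfs) {
    m <- do.call(rbind, strsplit(profiles[tfs], ""))
    paste(apply(m, 2L, function(col) names(sort(table(col),
                                                decreasing = TRUE))[1L]),
          collapse = "")
  }, character(1))
  out <- data.frame(tf = names(cl), cluster = unname(cl),
                    stringsAsFactors = FALSE)
  attr(out, "consensus") <- consensus
  attr(out, "tree") <- hc
  out
}
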