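# Growth-curve phenotyping: parameter extraction from OD600 time series
# and the t-test / Bonferroni / Stouffer comparison ladder for deletion
# versus control strains.

#' Collapse technical replicates by pointwise mean
#'
#' @param records data frame with columns `strain`, `bio_rep`, `tech_rep`,
#'   `time_h`, `od600`; technical replicates of one (strain, bio_rep) must
#'   share exactly the same time grid.
#' @return data frame `strain`, `bio_rep`, `time_h`, `od600`.
#' @export
collapse_technical <- function(records) {
  stopifnot(all(c("strain", "bio_rep", "tech_rep", "time_h", "od600") %in%
                  names(records)))
  key <- interaction(records$strain, records$bio_rep, drop = TRUE)
  for (k in levels(key)) {
    sub <- records[key == k, ]
    grids <- split(sub$time_h, sub$tech_rep)
    ref <- grids[[1L]]
    same <- vapply(grids, function(g)
      length(g) == length(ref) && all(g == ref), logical(1))
    if (!all(same)) {
      stop("technical replicates of ", k,
           " are on different time grids; refusing to interpolate",
           call. = FALSE)
    }
  }
  out <- aggregate(od600 ~ strain + bio_rep + time_h, data = records,
                   FUN = mean)
  out[order(out$strain, out$bio_rep, out$time_h), ]
}

#' Extract growth parameters from one OD600 curve
#'
#' The maximum specific growth rate `mu_max` is the largest least-squares
#' slope of `ln(OD)` versus time over a sliding window of `window`
#' consecutive points (2 h at 30-minute sampling with the default 5);
#' `t_mu_max` is the centre time of the earliest maximising window, and
#' `auc` the trapezoidal integral of OD over the full observed range.
#'
#' @param time_h,od numeric vectors (hours, OD600 > 0), equal length,
#'   strictly increasing times.
#' @param window sliding-window width in points (>= 2).
#' @param rate_scale slope of `log(OD)` (`"log"`, specific growth rate,
#'   default) or of raw OD (`"linear"`).
#' @return list with `mu_max` (per hour), `t_mu_max` (hours), `auc`
#'   (OD x hours).
#' @examples
#' t <- seq(0, 10, 0.5)
#' growth_parameters(t, 0.09 * exp(0.2 * t))$mu_max # exactly 0.2
#' @export
growth_parameters <- function(time_h, od, window = 5L,
                              rate_scale = c("log", "linear")) {
  rate_scale <- match.arg(rate_scale)
  n <- length(time_h)
  stopifnot(length(od) == n)
  if (any(diff(time_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(od <= 0)) stop("OD values must be positive", call. = FALSE)
  window <- .assert_scalar_count(window, "window")
  if (window > n) stop("window exceeds the number of points", call. = FALSE)
  y <- if (rate_scale == "log") log(od) else od
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- time_h[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  best <- which.max(slopes)[1L] # earliest maximising window wins ties
  centre <- mean(time_h[best:(best + window - 1L)])
  list(mu_max = slopes[best], t_mu_max = centre,
       auc = pracma::trapz(time_h, od))
}

#' Growth parameters for every (strain, biological replicate)
#'
#' @param curves collapsed curves from [collapse_technical()] (or any data
#'   frame with `strain`, `bio_rep`, `time_h`, `od600`).
#' @inheritParams growth_parameters
#' @return data frame `strain`, `bio_rep`, `mu_max`, `t_mu_max`, `auc`.
#' @export
growth_parameters_all <- function(curves, window = 5L,
                                  rate_scale = c("log", "linear")) {
  rate_scale <- match.arg(rate_scale)
  key <- unique(curves[, c("strain", "bio_rep")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- curves[curves$strain == key$strain[i] &
                    curves$bio_rep == key$bio_rep[i], ]
    sub <- sub[order(sub$time_h), ]
    gp <- growth_parameters(sub$time_h, sub$od600, window, rate_scale)
    data.frame(strain = key$strain[i], bio_rep = key$bio_rep[i],
               mu_max = gp$mu_max, t_mu_max = gp$t_mu_max, auc = gp$auc)
  })
  do.call(rbind, rows)
}

#' Combine p-values by Stouffer's Z-score method
#'
#' `Z = sum(qnorm(1 - p_i)) / sqrt(k)`, combined p `= 1 - pnorm(Z)`.
#' P-values are clamped away from 0 and 1 so degenerate inputs stay
#' finite.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return the combined p-value.
#' @examples
#' stouffer_combine(c(1.5e-2, 4.5e-2, 3.5e-3)) # ~7.5e-5
#' @export
stouffer_combine <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no p-values to combine", call. = FALSE)
  .assert_prob(p, "pvalues", open_left = TRUE)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  z <- qnorm(1 - p)
  pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
}

#' Compare growth parameters of two strains
#'
#' Two-sided unpaired t-tests per parameter (`mu_max`, `t_mu_max`, `auc`)
#' between the biological replicates of a deletion strain and its control,
#' Bonferroni correction by the number of strains compared in the wider
#' screen (capped at 1), and a Stouffer combination of the corrected
#' per-parameter p-values. Groups that are both constant give p = 1 when
#' the means agree.
#'
#' @param params_a,params_b data frames of per-replicate parameters (from
#'   [growth_parameters_all()]; one strain each).
#' @param n_comparisons Bonferroni factor (number of strains in the
#'   screen; default 8).
#' @return data frame with one row per parameter (`pvalue`,
#'   `bonferroni_p`) plus attributes `combined_p` (Stouffer over the
#'   corrected values) and `estimates`.
#' @export
compare_strains <- function(params_a, params_b, n_comparisons = 8L) {
  pars <- c("mu_max", "t_mu_max", "auc")
  pv <- sapply(pars, function(p) {
    x <- params_a[[p]]; y <- params_b[[p]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      stop("need >= 2 finite replicates per strain for ", p, call. = FALSE)
    }
    if (sd(x) == 0 && sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    t.test(x, y)$p.value
  })
  bonf <- pmin(pv * n_comparisons, 1)
  out <- data.frame(parameter = pars, pvalue = unname(pv),
                    bonferroni_p = unname(bonf))
  attr(out, "combined_p") <- stouffer_combine(bonf)
  attr(out, "estimates") <- rbind(a = colMeans(params_a[pars]),
                                  b = colMeans(params_b[pars]))
  out
}

#' Read / write growth-curve CSV files
#'
#' Columns: `strain`, `bio_rep`, `tech_rep`, `time_h`, `od600`.
#' @param path CSV path.
#' @export
read_growth_curves <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "bio_rep", "tech_rep", "time_h", "od600")
  if (!all(need %in% names(x))) {
    stop("growth CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname read_growth_curves
#' @param records growth data frame.
#' @export
write_growth_curves <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
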