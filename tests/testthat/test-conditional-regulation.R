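# toy compendium with one TF row and a controllable gene pool
toy_condreg <- function(n_genes = 8, n_arrays = 6, seed = 1,
                        tf_vals = NULL) {
  set.seed(seed)
  tf_vals <- tf_vals %||% seq(0, 1, length.out = n_arrays)
  m <- rbind(TF = tf_vals,
             matrix(rnorm(n_genes * n_arrays), n_genes, n_arrays,
                    dimnames = list(paste0("g", seq_len(n_genes)), NULL)))
  colnames(m) <- paste0("A", seq_len(n_arrays))
  make_compendium(m, list(CS1 = colnames(m)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fold-change filter works in log2 space", {
  m <- rbind(TF = c(0.1, 0.5, 1.0, 0.0, 0.3, 0.1),
             g1 = rnorm(6))
  colnames(m) <- paste0("A", 1:6)
  comp <- make_compendium(m, list(CS1 = paste0("A", 1:3),
                                  CS2 = paste0("A", 4:6)))
  # CS1 range 0.9 >= log2(1.75) ~ 0.807; CS2 range 0.3 fails
  pass <- filter_condition_sets(comp, "TF")
  expect_equal(pass, "CS1", ignore_attr = TRUE)
  fc <- attr(pass, "fold_change")
  expect_equal(unname(fc), c(0.9, 0.3))
  # degenerate threshold: every set passes at min_fold = 1
  expect_setequal(filter_condition_sets(comp, "TF", min_fold = 1),
                  c("CS1", "CS2"))
})

test_that("per-gene correlations hit the exact limits", {
  tfv <- c(0.1, 0.9, 0.3, 0.7, 0.5, 1.0)
  m <- rbind(TF = tfv, up1 = tfv, up2 = 2 * tfv + 1, down = -tfv,
             noise = c(0.2, 0.1, 0.4, 0.3, 0.9, 0.6))
  colnames(m) <- paste0("A", 1:6)
  comp <- make_compendium(m, list(CS1 = colnames(m)))
  r <- per_gene_correlations(comp, "TF", c("up1", "up2", "down"), "CS1")
  expect_equal(unname(r), c(1, 1, -1))
  expect_warning(
    r2 <- per_gene_correlations(comp, "TF", c("up1", "ghost"), "CS1"),
    "absent")
  expect_equal(names(r2), "up1")
})

test_that("median statistic and role proposal follow the order statistics", {
  expect_equal(median_statistic(c(0.9, 0.8, 0.5, 0.2, -0.1)), 0.5)
  expect_equal(median_statistic(c(-0.7, -0.6, 0.1)), -0.6)
  expect_equal(median_statistic(c(-0.3, 0.3)), 0)
  expect_error(median_statistic(rep(NA_real_, 3)), "undefined")
})

test_that("gene selection keeps the strictly-above/below-median halves", {
  r <- c(a = 0.9, b = 0.8, c = 0.5, d = 0.2, e = -0.1)
  expect_setequal(select_conditional_genes(r, "activator"), c("a", "b"))
  expect_setequal(select_conditional_genes(r, "repressor"), c("d", "e"))
  expect_length(select_conditional_genes(rep(0.4, 5), "activator"), 0L)
  set.seed(1)
  for (n in c(7, 10, 25)) {
    rr <- setNames(runif(n, -1, 1), paste0("g", 1:n))
    expect_length(select_conditional_genes(rr, "activator"), floor(n / 2))
  }
})

test_that("BH adjustment equals the hand step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    # independent step-up oracle
    o <- order(p)
    m <- length(p)
    stepped <- rev(cummin(rev(m * p[o] / seq_len(m))))
    oracle <- pmin(stepped, 1)[order(o)]
    expect_equal(q, oracle)
    expect_true(all(q >= p))
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("permutation p-value agrees with exhaustive enumeration", {
  comp <- toy_condreg(n_genes = 5, n_arrays = 8, seed = 3)
  r_all <- per_gene_correlations(comp, "TF", paste0("g", 1:5), "CS1",
                                 min_arrays = 6)
  # exact null: all C(5,2) = 10 gene pairs
  pairs <- combn(5, 2)
  exact_meds <- apply(pairs, 2, function(ix) median(r_all[ix]))
  obs <- median(r_all[c(1, 2)])
  exact_p <- mean(exact_meds >= obs)
  p <- permutation_pvalue(comp, "TF", 2, "CS1", obs, tail = "upper",
                          n_perm = 4000, seed = 9)
  se <- sqrt(exact_p * (1 - exact_p) / 4000)
  expect_lt(abs(as.numeric(p) - exact_p), 3 * se + 1 / 4001)
  # lower tail mirrors
  p_lo <- permutation_pvalue(comp, "TF", 2, "CS1", obs, tail = "lower",
                             n_perm = 4000, seed = 9)
  exact_lo <- mean(exact_meds <= obs)
  expect_lt(abs(as.numeric(p_lo) - exact_lo),
            3 * sqrt(exact_lo * (1 - exact_lo) / 4000) + 1 / 4001)
})

test_that("permutation p-value floor and centre behave as an estimator", {
  comp <- toy_condreg(n_genes = 30, n_arrays = 10, seed = 4)
  # observed beyond every draw: p equals the +1/(N+1) floor
  p <- permutation_pvalue(comp, "TF", 5, "CS1", 2, tail = "upper",
                          n_perm = 2000, seed = 1)
  expect_equal(as.numeric(p), 1 / 2001)
  # the universe median sits near the null centre
  r_all <- per_gene_correlations(comp, "TF", paste0("g", 1:30), "CS1",
                                 min_arrays = 6)
  p_mid <- permutation_pvalue(comp, "TF", 5, "CS1", median(r_all),
                              tail = "upper", n_perm = 4000, seed = 2)
  expect_gt(as.numeric(p_mid), 0.3)
  expect_lt(as.numeric(p_mid), 0.7)
  expect_error(permutation_pvalue(comp, "TF", 0, "CS1", 0), "positive")
  expect_error(permutation_pvalue(comp, "TF", 31, "CS1", 0),
               "exceeds the gene universe")
})

test_that("dispersion filter detects constructed coupling and fails closed", {
  set.seed(6)
  n_arr <- 14
  tfv <- seq(0.05, 1.6, length.out = n_arr)
  # targets: common level c*TF, per-gene offsets spread proportional to TF
  targets <- t(sapply(1:12, function(i) 0.8 * tfv + rnorm(1) * tfv * 0.5))
  rownames(targets) <- paste0("t", 1:12)
  pool <- matrix(rnorm(60 * n_arr, 0, 0.3), 60, n_arr,
                 dimnames = list(paste0("g", 1:60), NULL))
  m <- rbind(TF = tfv, targets, pool)
  colnames(m) <- paste0("A", seq_len(n_arr))
  comp <- make_compendium(m, list(CS1 = colnames(m)))
  res <- dispersion_coupling_filter(comp, "TF", paste0("t", 1:12), "CS1",
                                    n_perm = 1000, seed = 3)
  expect_gt(res$statistic, 0.8)
  expect_lt(res$pvalue, 0.05)
  # constant targets: statistic undefined, filter fails closed
  m2 <- m
  m2[paste0("t", 1:12), ] <- 1
  comp2 <- make_compendium(m2, list(CS1 = colnames(m2)))
  expect_warning(
    res2 <- dispersion_coupling_filter(comp2, "TF", paste0("t", 1:12),
                                       "CS1", n_perm = 200, seed = 1),
    "fails closed")
  expect_true(is.na(res2$pvalue))
})

test_that("dispersion p-values are roughly uniform for unrelated targets", {
  ps <- vapply(1:20, function(s) {
    comp <- toy_condreg(n_genes = 40, n_arrays = 12, seed = 100 + s)
    dispersion_coupling_filter(comp, "TF", paste0("g", 1:10), "CS1",
                               n_perm = 400, seed = s)$pvalue
  }, numeric(1))
  # no mass piling up at the significant end
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps <= 0.05), 0.25)
})

test_that("call_regulons is reproducible and order-invariant", {
  st <- small_planted_study(seed = 19)
  tm <- st$truth$targets
  c1 <- suppressWarnings(call_regulons(st$compendium, tm, n_perm = 300,
                                       seed = 8))
  c2 <- suppressWarnings(call_regulons(st$compendium, tm, n_perm = 300,
                                       seed = 8))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "selected"), attr(c2, "selected"))
  # permute gene rows, array columns and TF order: identical output
  ex <- st$compendium$exprs
  set.seed(1)
  ex2 <- ex[sample(nrow(ex)), sample(ncol(ex))]
  comp2 <- new_compendium(ex2, st$compendium$manifest)
  tm2 <- rev(lapply(tm, rev))
  c3 <- suppressWarnings(call_regulons(comp2, tm2, n_perm = 300, seed = 8))
  expect_identical(as.data.frame(c1), as.data.frame(c3))
})

test_that("planted activators and repressors recover their signs", {
  st <- small_planted_study(seed = 23)
  calls <- suppressWarnings(
    call_regulons(st$compendium, st$truth$targets, n_perm = 1000, seed = 5,
                  dispersion_filter = FALSE))
  df <- as.data.frame(calls)
  pl <- st$truth$planted
  for (i in seq_len(nrow(pl))) {
    row <- df[df$tf == pl$tf_id[i] & df$condition_set ==
                pl$condition_set_id[i] & df$role == pl$role[i], ]
    expect_equal(nrow(row), 1L)
    expect_true(row$called)
    if (pl$role[i] == "activator") expect_gt(row$median_r, 0.4)
    else expect_lt(row$median_r, -0.4)
    key <- paste(pl$tf_id[i], pl$condition_set_id[i], pl$role[i], sep = "|")
    sel <- attr(calls, "selected")[[key]]
    expect_gt(length(sel), 0L)
    expect_true(all(sel %in% st$truth$targets[[pl$tf_id[i]]]))
  }
})

test_that("regulon calls can be written with their gene lists", {
  st <- small_planted_study(seed = 23)
  calls <- suppressWarnings(
    call_regulons(st$compendium, st$truth$targets, n_perm = 500, seed = 5,
                  dispersion_filter = FALSE))
  out <- tempfile(fileext = ".tsv")
  gdir <- tempfile()
  write_regulon_calls(calls, out, gdir)
  back <- read.delim(out)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(length(list.files(gdir)),
               length(attr(calls, "selected")))
})
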