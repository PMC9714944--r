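test_that("copies_from_mass uses the 6.7 pg diploid genome", {
  expect_equal(copies_from_mass(2.5), 373.6, tolerance = 1e-3)
  expect_equal(copies_from_mass(5), 2 * copies_from_mass(2.5))
  # the lowest calibration input spans roughly 400-1200 copies at 1-3
  # copies per diploid genome
  span <- copies_from_mass(2.5, c(1, 3))
  expect_equal(round(span, -2), c(400, 1100))
  expect_error(copies_from_mass(-1), "positive")
})

test_that("calibration fits report slope, efficiency and degeneracy", {
  copies <- rep(copies_from_mass(c(2.5, 5, 10, 20, 40, 80), 2), each = 3)
  cq <- 26 - log2(copies / copies_from_mass(10, 2))
  fit <- fit_calibration(copies, cq)
  expect_equal(round(fit$slope, 3), -3.322)
  expect_equal(fit$efficiency, 1, tolerance = 5e-4)
  expect_equal(fit$r2, 1)
  # efficiency convention: slope -3.6 -> 0.896
  expect_equal(round(10^(-1 / -3.6) - 1, 3), 0.896)
  f36 <- fit_calibration(copies, -3.6 * log10(copies))
  expect_equal(round(f36$efficiency, 3), 0.896)
  # efficiency strictly increasing in slope on the negative axis
  effs <- vapply(c(-4, -3.6, -3.322, -3), function(s) 10^(-1 / s) - 1,
                 numeric(1))
  expect_true(all(diff(effs) > 0))
  expect_warning(fit_calibration(copies, rep(26, length(copies))),
                 "degenerate")
  expect_error(fit_calibration(c(1, 1, 2, 2), c(25, 25, 24, 24)),
               "3 distinct")
})

test_that("Hubaux-Vos LOD shrinks with noise and with looser rates", {
  set.seed(17)
  copies <- rep(copies_from_mass(c(2.5, 5, 10, 20, 40, 80), 2), each = 3)
  b <- 1e-8
  make_cq <- function(s) {
    y <- b * copies + rnorm(length(copies), 0, s)
    -log2(pmax(y, 1e-12))
  }
  cq <- make_cq(2e-6)
  lod <- lod_hubaux_vos(copies, cq)
  expect_gt(lod$lod_copies, 0)
  # doubling alpha and beta strictly decreases the LOD
  lod2 <- lod_hubaux_vos(copies, cq, alpha = 0.1, beta = 0.1)
  expect_lt(lod2$lod_copies, lod$lod_copies)
  # vanishing residual noise drives the LOD toward zero
  lod_small <- lod_hubaux_vos(copies, make_cq(2e-8))
  expect_lt(lod_small$lod_copies, lod$lod_copies / 10)
})

test_that("Hubaux-Vos LOD matches a Monte-Carlo error-rate search", {
  set.seed(29)
  copies <- rep(copies_from_mass(c(2.5, 5, 10, 20, 40, 80), 2), each = 3)
  y <- 1e-8 * copies + rnorm(length(copies), 0, 2e-6)
  cq <- -log2(y)
  lod <- lod_hubaux_vos(copies, cq)
  # oracle: treat the fitted line as truth, simulate prediction errors,
  # find the concentration whose false-negative rate against the
  # empirical blank decision limit equals beta
  n <- lod$n; xbar <- mean(copies); sxx <- sum((copies - xbar)^2)
  sepred <- function(x0) lod$residual_sd *
    sqrt(1 + 1 / n + (x0 - xbar)^2 / sxx)
  draws <- 1e5
  yc_mc <- quantile(lod$intercept + rnorm(draws, 0, sepred(0)), 0.95)
  fn_rate <- function(x0)
    mean(lod$intercept + lod$slope * x0 +
           rnorm(draws, 0, sepred(x0)) < yc_mc)
  grid <- seq(0.2, 3, by = 0.01) * lod$lod_copies
  mc_lod <- grid[which(vapply(grid, fn_rate, numeric(1)) <= 0.05)[1]]
  expect_equal(lod$lod_copies, mc_lod, tolerance = 0.1)
})

test_that("pooled CV pools squared CVs by degrees of freedom", {
  expect_equal(pooled_cv(list(c(5, 5, 5), c(9, 9))), 0)
  one <- c(10, 11, 9)
  expect_equal(pooled_cv(list(one)), 100 * sd(one) / mean(one))
  # CVs of 1% and 3% with equal df pool to sqrt(5) ~ 2.236%
  g1 <- c(99, 101); g2 <- c(97, 103)
  expect_equal(100 * sd(g1) / mean(g1), sqrt(2), tolerance = 1e-9)
  cvs <- c(0.01, 0.03)
  mk <- function(cv) 100 * c(1 - cv / sqrt(2), 1 + cv / sqrt(2))
  expect_equal(pooled_cv(list(mk(0.01), mk(0.03))), sqrt(5),
               tolerance = 1e-9)
  expect_warning(pooled_cv(list(c(1, 2), c(-3, -1))), "non-positive")
  expect_error(pooled_cv(list(c(-3, -1))) |> suppressWarnings(), "no usable")
})

test_that("reproducibility pooled CV exceeds repeatability with run shifts", {
  set.seed(41)
  diffs <- replicate(60, {
    co <- simulate_cohort(cohort_spec(2), noise_spec(run_sd = 0.3))
    pr <- precision_report(co$cq)
    ref <- pr[pr$channel == "reference", ]
    mean(ref$pooled_cv_percent[ref$scope == "reproducibility"]) -
      mean(ref$pooled_cv_percent[ref$scope == "repeatability"])
  })
  expect_gt(mean(diffs), 0)
})

test_that("NRMSE measures target-Cq tracking of the reference channel", {
  ref <- c(26.0, 26.1, 25.9)
  tgt <- ref + 1 - log2(3)
  expect_equal(nrmse(tgt, ref, 3), 0)
  # constant bias b on every well -> b / mean(observed)
  expect_equal(nrmse(tgt + 0.2, ref, 3), 0.2 / mean(tgt + 0.2))
  # adding a constant to both channels leaves the numerator unchanged
  num <- function(t, r) nrmse(t, r, 3) * mean(t)
  expect_equal(num(tgt + 0.1 + 5, ref + 5), num(tgt + 0.1, ref))
  expect_error(nrmse(tgt, ref, 0), "GCN 0")
})

test_that("per-sample NRMSE tracks the accuracy of the measured GCNs", {
  set.seed(53)
  co <- simulate_cohort(cohort_spec(30),
                        noise_spec(asym_matrix_sd = 0.15, well_sd = 0.03),
                        seed = 53)
  nr <- nrmse_report(co$cq, co$truth)
  m <- measure_gcns(co$cq)
  s <- m$samples
  ints <- mapply(function(sid, a) co$truth[[a]][co$truth$sample_id == sid],
                 s$sample_id, s$assay_id)
  keep <- ints >= 1
  re <- abs(relative_error(s$mean[keep], ints[keep]))
  re_by_sample <- tapply(re, s$sample_id[keep], mean)
  nr_by_sample <- tapply(nr$nrmse, nr$sample_id, mean)
  ids <- intersect(names(re_by_sample), names(nr_by_sample))
  rho <- cor(re_by_sample[ids], nr_by_sample[ids], method = "spearman")
  expect_gt(rho, 0)
})
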