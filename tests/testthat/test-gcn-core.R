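test_that("gcn_from_cq inverts the delta-Cq relation", {
  expect_equal(gcn_from_cq(26, 26), 2)
  expect_equal(gcn_from_cq(27, 26), 1)
  expect_equal(round(gcn_from_cq(25.415, 26), 3), 3)
  # exact recovery for n = 1..6 and strict monotonicity in the target Cq
  for (n in 1:6)
    expect_equal(gcn_from_cq(26 + 1 - log2(n), 26), n)
  cqs <- seq(24, 28, by = 0.25)
  expect_true(all(diff(gcn_from_cq(cqs, 26)) < 0))
  # dropout target -> 0; absent reference invalid
  expect_equal(gcn_from_cq(NA, 26), 0)
  expect_error(gcn_from_cq(26, NA), "reference")
  # offset acts multiplicatively as 2^offset
  expect_equal(gcn_from_cq(26, 26, offset = 1), 4)
})

test_that("consecutive-GCN Cq gaps shrink as log2((n+1)/n)", {
  gaps <- vapply(1:5, function(n) {
    (26 + 1 - log2(n)) - (26 + 1 - log2(n + 1))
  }, numeric(1))
  expect_equal(gaps, log2((2:6) / (1:5)))
  expect_true(all(diff(gaps) < 0))
})

test_that("tune_offset drives the mean relative error to zero", {
  expect_equal(tune_offset(c(2, 3, 4), c(2, 3, 4)), 0)
  expect_equal(tune_offset(c(4, 6), c(2, 3)), -1)         # all ratios 2
  expect_equal(tune_offset(c(1.25, 0.75), c(1, 1)), 0)    # mean ratio 1
  expect_error(tune_offset(c(1, 2), c(0, 0)), "GCN >= 1")
  # property: on random cohorts the post-tuning mean RE is 0 to 1e-9
  set.seed(31)
  for (rep in 1:20) {
    ints <- sample(1:4, 50, replace = TRUE)
    meas <- ints * (1 + rnorm(50, 0.05, 0.08))
    o <- tune_offset(meas, ints)
    expect_lt(abs(mean(relative_error(meas * 2^o, ints))), 1e-9)
  }
})

test_that("relative_error is the signed fractional deviation", {
  expect_equal(relative_error(2.2, 2), 0.1)
  expect_equal(relative_error(3, 3), 0)
  expect_equal(relative_error(1.8, 2), -0.1)
  expect_error(relative_error(1, 0), "undefined")
})

test_that("aggregate_replicates excludes dropouts from dispersion", {
  a <- aggregate_replicates(c(2, 2, 2))
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 0)
  expect_equal(a$cv_percent, 0)
  b <- aggregate_replicates(c(1.9, 2.0, 2.1))
  expect_equal(b$mean, 2)
  expect_equal(b$sd, 0.1)
  d <- aggregate_replicates(c(0, 2, 2))
  expect_equal(d$mean, 2)
  expect_equal(d$n_dropout, 1)
  expect_equal(d$n, 2)
  e <- aggregate_replicates(c(0, 0))
  expect_equal(e$mean, 0)
  expect_true(e$all_dropout)
  expect_true(is.na(e$sd))
})

test_that("the ambiguity rule partitions the measured-GCN axis", {
  expect_equal(classify_ambiguity(2.25)$label, "unambiguous")
  expect_equal(classify_ambiguity(2.25)$integer, 2)
  expect_equal(classify_ambiguity(2.45)$label, "ambiguous")
  # boundary inclusive: 1.70 is exactly 0.3 from 2
  expect_equal(classify_ambiguity(1.70)$integer, 2)
  # every value gets exactly one label, invariant under integer shifts
  x <- seq(0, 0.999, by = 0.001)
  for (shift in c(0, 1, 3)) {
    cls <- classify_ambiguity(x + shift)
    expect_true(all(cls$label %in% c("unambiguous", "ambiguous")))
    if (shift > 0)
      expect_equal(cls$label, classify_ambiguity(x + 1)$label)
  }
})

test_that("expected GCNs share the constraint-mean total across pairs", {
  m <- setNames(c(2, 2, 1.5, 1.5, 1.5, 1.5, 1), rccx_assays())
  e <- expected_gcn(m)
  expect_equal(e$expected_total, 3.25)
  loci <- e$loci
  expect_equal(loci$expected[loci$assay_id == "C4A"], 1.625)
  expect_equal(loci$deviation[loci$assay_id == "C4A"], 0.375)
  expect_false(loci$inconsistent[loci$assay_id == "C4A"])
  # exact agreement -> zero deviations, no flags
  m0 <- setNames(c(1, 2, 1, 2, 2, 1, 1), rccx_assays())
  e0 <- expected_gcn(m0)
  expect_equal(e0$loci$deviation, rep(0, 7))
  expect_false(any(e0$loci$inconsistent))
  # a constructed deviation above 0.4 is flagged
  m1 <- m0
  m1["C4A"] <- 1 + 1.2   # pulls C4A away while inflating the C4 total
  e1 <- expected_gcn(m1)
  expect_true(e1$loci$inconsistent[e1$loci$assay_id == "C4A"])
  # pair summing to zero: expected 0, never flagged
  m2 <- setNames(c(0, 2, 0, 2, 2, 0, 0), rccx_assays())
  e2 <- expected_gcn(m2)
  expect_equal(e2$loci$expected[e2$loci$assay_id == "C4A"], 0)
  expect_false(e2$loci$inconsistent[e2$loci$assay_id == "C4A"])
})

test_that("measure_gcns pairs wells and aggregates per sample", {
  g <- rccx_genotype(rccx_haplotype("B", "A2", "deletion"),
                     rccx_haplotype(c("A", "B"), c("A1P", "A2"),
                                    c("insertion", "deletion")))
  cq <- simulate_cq(g, noiseless_spec(), cohort_spec(1))
  m <- measure_gcns(cq)
  expect_s3_class(m, "rccx_measured")
  w <- measured_wide(m)
  expect_equal(unname(unlist(w[1, rccx_assays()])),
               unname(as.numeric(g$gcn)))
  expect_equal(m$samples$sd[!is.na(m$samples$sd)],
               rep(0, sum(!is.na(m$samples$sd))))
})

test_that("offset calibration recovers an injected assay bias", {
  set.seed(5)
  ns <- noise_spec(well_sd = 0.02, asym_matrix_sd = 0,
                   assay_bias = c(C4A = 0.4))
  co <- simulate_cohort(cohort_spec(12), ns, seed = 5)
  cfg <- calibrate_offsets(co$cq, truth = co$truth, groups = co$meta)
  # the C4A offset must compensate the +0.4 cycle bias
  expect_equal(unname(cfg$offsets["C4A"]), 0.4, tolerance = 0.05)
  m <- measure_gcns(co$cq, cfg)
  w <- m$wells[m$wells$assay_id == "C4A", ]
  ints <- co$truth$C4A[match(w$sample_id, co$truth$sample_id)]
  keep <- ints >= 1 & co$meta$study_group[
    match(w$sample_id, co$meta$sample_id)] %in% c("good", "population")
  expect_lt(abs(mean(relative_error(w$gcn[keep], ints[keep]))), 1e-9)
  # iterative self-rounding scheme lands near the same offsets
  cfg2 <- calibrate_offsets(co$cq, groups = co$meta)
  expect_equal(unname(cfg2$offsets["C4A"]), unname(cfg$offsets["C4A"]),
               tolerance = 0.05)
})
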