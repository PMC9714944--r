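test_that("genotype GCN counting follows the segment composition", {
  g <- rccx_genotype(
    rccx_haplotype("B", "A2", "deletion"),
    rccx_haplotype(c("A", "B"), c("A1P", "A2"),
                   c("insertion", "deletion")))
  expect_equal(g$total, 3)
  expect_equal(unname(g$gcn[c("C4A", "C4B", "BP")]), c(1L, 2L, 1L))

  both_mono <- rccx_genotype(rccx_haplotype("B", "A2", "deletion"),
                             rccx_haplotype("A", "A2", "insertion"))
  expect_equal(both_mono$total, 2)
  expect_equal(unname(both_mono$gcn["BP"]), 0L)
})

test_that("every sampled genotype satisfies the four-way total equality", {
  set.seed(11)
  for (g in sample_genotypes(10000)) {
    gc <- g$gcn
    totals <- c(gc[["C4A"]] + gc[["C4B"]],
                gc[["CYP21A1P"]] + gc[["CYP21A2"]],
                gc[["HERV_del"]] + gc[["HERV_ins"]],
                gc[["BP"]] + 2L)
    if (!all(totals == g$total) || any(gc < 0))
      fail(sprintf("constraint violated: totals %s vs %d",
                   paste(totals, collapse = "/"), g$total))
  }
  succeed()
})

test_that("haplotype frequencies are recovered from genotype draws", {
  set.seed(7)
  p <- 0.7
  gs <- sample_genotypes(5000, two_hap_freqs(p))  # 10,000 haplotype draws
  n_mono <- sum(vapply(gs, function(g)
    (nrow(g$hap1) == 1) + (nrow(g$hap2) == 1), numeric(1)))
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(n_mono / 10000 - p), 3 * se)
})

test_that("sampling rejects invalid frequency maps", {
  expect_error(sample_genotype(list(haplotypes = list(), freqs = numeric(0))),
               "empty")
  bad <- two_hap_freqs()
  bad$freqs <- c(0.5, 0.4)
  expect_error(sample_genotype(bad), "sum to 1")
})

test_that("noiseless Cq differences encode the copy number exactly", {
  design <- cohort_spec(1, wells_per_run = 2, runs = 1)
  g2 <- rccx_genotype(rccx_haplotype("A", "A1P", "insertion"),
                      rccx_haplotype("B", "A2", "deletion"))
  cq <- simulate_cq(g2, noiseless_spec(), design)
  dcq <- function(d, assay) {
    t <- d[d$assay_id == assay & d$channel == "target", "cq"]
    r <- d[d$assay_id == assay & d$channel == "reference", "cq"]
    t - r
  }
  # GCN 2 -> delta Cq 0; GCN 1 -> delta Cq 1 (C4A has one copy here)
  expect_equal(dcq(cq, "HERV_del"), c(1, 1))   # HERV_del GCN 1
  expect_equal(dcq(cq, "C4A"), c(1, 1))
  g22 <- rccx_genotype(rccx_haplotype("A", "A2", "insertion"),
                       rccx_haplotype("A", "A2", "insertion"))
  cq22 <- simulate_cq(g22, noiseless_spec(), design)
  expect_equal(dcq(cq22, "C4A"), c(0, 0))      # GCN 2 -> 0 exactly
  # zero-copy locus: no target amplification, dropout flagged
  bp <- cq22[cq22$assay_id == "BP" & cq22$channel == "target", ]
  expect_true(all(is.na(bp$cq)))
  expect_true(all(bp$dropout))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_spec(4), noise_spec(), seed = 99)
  b <- simulate_cohort(cohort_spec(4), noise_spec(), seed = 99)
  expect_identical(a$cq, b$cq)
  expect_identical(a$truth, b$truth)
})

test_that("within-sample delta-Cq noise is sqrt(2) times the well SD", {
  set.seed(23)
  g <- rccx_genotype(rccx_haplotype("A", "A2", "insertion"),
                     rccx_haplotype("A", "A2", "insertion"))
  ns <- noise_spec(matrix_sd = 0, run_sd = 0, asym_matrix_sd = 0,
                   well_sd = 0.05)
  cq <- simulate_cq(g, ns, cohort_spec(1, wells_per_run = 1000, runs = 10))
  sub <- cq[cq$assay_id == "C4A", ]
  t <- sub$cq[sub$channel == "target"]
  r <- sub$cq[sub$channel == "reference"]
  expect_equal(sd(t - r), sqrt(2) * 0.05, tolerance = 0.05)
})

test_that("dilution series follows perfect doubling and the -3.322 slope", {
  g <- rccx_genotype(rccx_haplotype("A", "A1P", "insertion"),
                     rccx_haplotype("B", "A2", "deletion"))
  ser <- simulate_dilution_series(g, noiseless_spec(),
                                  masses = c(2.5, 5, 10, 20, 40, 80),
                                  replicates = 1)
  ref <- ser[ser$assay_id == "C4A" & ser$channel == "reference", ]
  ref <- ref[order(ref$mass_ng), ]
  expect_equal(diff(ref$cq), rep(-1, 5))
  fit <- lm(cq ~ log10(copies), data = ref)
  expect_equal(round(unname(coef(fit)[2]), 3), -3.322)
  # doubling the genotype GCN (2 -> 4) shifts the target curve by exactly 1
  g2c <- rccx_genotype(rccx_haplotype("A", "A2", "insertion"),
                       rccx_haplotype("A", "A2", "insertion"))
  g4 <- rccx_genotype(rccx_haplotype(c("A", "A"), c("A1P", "A2"),
                                     c("insertion", "insertion")),
                      rccx_haplotype(c("A", "A"), c("A1P", "A2"),
                                     c("insertion", "insertion")))
  s2 <- simulate_dilution_series(g2c, noiseless_spec(), replicates = 1)
  s4 <- simulate_dilution_series(g4, noiseless_spec(), replicates = 1)
  t2 <- s2[s2$assay_id == "C4A" & s2$channel == "target", ]
  t4 <- s4[s4$assay_id == "C4A" & s4$channel == "target", ]
  expect_equal(t2$cq - t4$cq, rep(1, nrow(t2)))
  expect_error(simulate_dilution_series(g, masses = c(-1, 5)), "positive")
})
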