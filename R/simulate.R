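#' Noise specification for synthetic Cq data
#'
#' Parameterises the error structure of simulated duplex qPCR reactions.
#' The dominant term is a per-sample "matrix effect": a normal shift of the
#' reference-gene Cq shared by both channels of a sample (so it cancels in
#' the Cq difference), reflecting the large between-sample spread of
#' reference Cq seen in genomic DNA backgrounds. A small channel-asymmetric
#' matrix component (`asym_matrix_sd`, applied to the target channel only)
#' does not cancel and is what limits accuracy. Between-run (day) shifts
#' are shared by both channels of a well; within-run well noise is drawn
#' independently per channel.
#'
#' @param base_ref_cq Mean reference-gene Cq at the standard 10 ng input,
#'   cycles. Default 26.0724.
#' @param matrix_sd SD of the per-sample channel-symmetric matrix shift,
#'   cycles. Default 0.5.
#' @param well_sd SD of independent per-well, per-channel noise, cycles.
#'   Default 0.05.
#' @param run_sd SD of the per-run (between-day) shift, cycles. Default 0.1.
#' @param asym_matrix_sd SD of the per-sample, per-assay channel-asymmetric
#'   matrix component, cycles. Default 0.02.
#' @param assay_bias Named numeric vector of fixed target-channel biases per
#'   assay, cycles. Default all 0.
#' @param degraded_extra_sd Extra target-channel well noise for degraded
#'   ("bad quality") samples, cycles. Default 0.1.
#' @param degraded_bias Fixed target-channel bias for degraded samples,
#'   cycles, emulating the sensitivity of CYP21 assays to DNA degradation.
#'   Default 0.05.
#' @return Object of class `rccx_noise_spec`.
#' @export
noise_spec <- function(base_ref_cq = 26.0724, matrix_sd = 0.5,
                       well_sd = 0.05, run_sd = 0.1, asym_matrix_sd = 0.02,
                       assay_bias = NULL, degraded_extra_sd = 0.1,
                       degraded_bias = 0.05) {
  sds <- c(matrix_sd, well_sd, run_sd, asym_matrix_sd, degraded_extra_sd)
  if (any(sds < 0)) stop("all noise SDs must be >= 0")
  bias <- setNames(numeric(length(rccx_assays())), rccx_assays())
  if (!is.null(assay_bias)) {
    check_assay_ids(names(assay_bias))
    bias[names(assay_bias)] <- assay_bias
  }
  structure(list(base_ref_cq = base_ref_cq, matrix_sd = matrix_sd,
                 well_sd = well_sd, run_sd = run_sd,
                 asym_matrix_sd = asym_matrix_sd, assay_bias = bias,
                 degraded_extra_sd = degraded_extra_sd,
                 degraded_bias = degraded_bias),
            class = "rccx_noise_spec")
}

#' A noiseless specification (all SDs and biases zero)
#'
#' Convenience for exact-recovery checks: Cq values become deterministic
#' functions of the genotype.
#'
#' @param base_ref_cq Mean reference Cq, cycles.
#' @return An `rccx_noise_spec` with every stochastic term set to 0.
#' @export
noiseless_spec <- function(base_ref_cq = 26.0724) {
  noise_spec(base_ref_cq = base_ref_cq, matrix_sd = 0, well_sd = 0,
             run_sd = 0, asym_matrix_sd = 0, degraded_extra_sd = 0,
             degraded_bias = 0)
}

#' Cohort design for simulation
#'
#' @param n_samples Number of samples. Default 46.
#' @param wells_per_run Technical replicate wells per run. Default 3.
#' @param runs Number of runs (days). Default 3.
#' @param quality_fractions Named fractions of `good` / `population` / `bad`
#'   quality samples; must sum to 1. Defaults 17/46, 19/46, 10/46.
#' @return Object of class `rccx_cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 46, wells_per_run = 3, runs = 3,
                        quality_fractions = c(good = 17 / 46,
                                              population = 19 / 46,
                                              bad = 10 / 46)) {
  stopifnot(n_samples >= 1, wells_per_run >= 1, runs >= 1)
  if (abs(sum(quality_fractions) - 1) > 1e-9)
    stop("quality fractions must sum to 1")
  stopifnot(all(names(quality_fractions) %in% c("good", "population", "bad")))
  structure(list(n_samples = as.integer(n_samples),
                 wells_per_run = as.integer(wells_per_run),
                 runs = as.integer(runs),
                 quality_fractions = quality_fractions),
            class = "rccx_cohort_spec")
}

#' Simulate duplex Cq records for one sample
#'
#' Generates the long-format Cq table for one genotype across the seven
#' assays. For each well, the reference Cq is `base_ref_cq + matrix shift +
#' run shift + well noise` and the target Cq adds `1 - log2(GCN)` (the
#' relative-quantification relation between Cq difference and copy number),
#' the assay bias, the channel-asymmetric matrix component and, for "bad"
#' quality samples, the degradation bias and extra noise. Loci with GCN = 0
#' produce no target amplification: the target Cq is `NA` and the record is
#' flagged as a dropout. The reference channel never drops out.
#'
#' Random draws occur in a fixed, documented order (matrix shift; per-assay
#' asymmetric shifts; per-assay-and-run shifts; per-well reference then
#' target noise), so results are reproducible under a fixed seed.
#'
#' @param genotype An `rccx_genotype`.
#' @param noise An `rccx_noise_spec`.
#' @param design An `rccx_cohort_spec` (only `wells_per_run` and `runs` are
#'   used).
#' @param sample_id Sample identifier.
#' @param quality One of "good", "population", "bad".
#' @return data.frame with columns `sample_id`, `assay_id`, `channel`,
#'   `run`, `replicate`, `cq`, `dropout`.
#' @export
simulate_cq <- function(genotype, noise = noise_spec(),
                        design = cohort_spec(), sample_id = "S001",
                        quality = c("good", "population", "bad")) {
  quality <- match.arg(quality)
  stopifnot(inherits(genotype, "rccx_genotype"),
            inherits(noise, "rccx_noise_spec"))
  assays <- rccx_assays()
  runs <- design$runs
  wells <- design$wells_per_run
  matrix_shift <- rnorm(1, 0, noise$matrix_sd)
  asym <- setNames(rnorm(length(assays), 0, noise$asym_matrix_sd), assays)
  out <- vector("list", length(assays))
  tgt_sd <- sqrt(noise$well_sd^2 +
                 (if (quality == "bad") noise$degraded_extra_sd^2 else 0))
  tgt_bias <- if (quality == "bad") noise$degraded_bias else 0
  for (a in seq_along(assays)) {
    assay <- assays[a]
    gcn <- genotype$gcn[[assay]]
    run_shift <- rnorm(runs, 0, noise$run_sd)
    rows <- vector("list", runs)
    for (r in seq_len(runs)) {
      eps_ref <- rnorm(wells, 0, noise$well_sd)
      eps_tgt <- rnorm(wells, 0, tgt_sd)
      cq_ref <- noise$base_ref_cq + matrix_shift + run_shift[r] + eps_ref
      if (gcn >= 1) {
        cq_tgt <- cq_ref - eps_ref + 1 - log2(gcn) +
          noise$assay_bias[[assay]] + asym[[assay]] + tgt_bias + eps_tgt
        drop <- rep(FALSE, wells)
      } else {
        cq_tgt <- rep(NA_real_, wells)
        drop <- rep(TRUE, wells)
      }
      rows[[r]] <- data.frame(
        sample_id = sample_id, assay_id = assay,
        channel = rep(c("reference", "target"), each = wells),
        run = r, replicate = rep(seq_len(wells), 2),
        cq = c(cq_ref, cq_tgt),
        dropout = c(rep(FALSE, wells), drop),
        stringsAsFactors = FALSE)
    }
    out[[a]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full study cohort
#'
#' Draws genotypes from a haplotype frequency table, assigns quality
#' groups, and simulates the replicate Cq structure for every sample.
#'
#' @param design An `rccx_cohort_spec`.
#' @param noise An `rccx_noise_spec`.
#' @param freqs Haplotype frequency table, see [default_haplotype_freqs()].
#' @param seed Optional integer seed; when given, `set.seed(seed)` is
#'   called so the cohort is fully reproducible.
#' @return List with `cq` (long Cq table), `truth` (integer GCNs per
#'   sample) and `meta` (`sample_id`, `study_group`).
#' @export
simulate_cohort <- function(design = cohort_spec(), noise = noise_spec(),
                            freqs = default_haplotype_freqs(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_samples
  qf <- design$quality_fractions
  counts <- floor(qf * n)
  while (sum(counts) < n) counts[which.max(qf * n - counts)] <-
    counts[which.max(qf * n - counts)] + 1
  groups <- sample(rep(names(counts), counts))
  genotypes <- sample_genotypes(n, freqs)
  ids <- sprintf("S%03d", seq_len(n))
  cq <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_cq(genotypes[[i]], noise, design, ids[i], groups[i])))
  list(cq = cq,
       truth = genotype_truth(genotypes, ids),
       meta = data.frame(sample_id = ids, study_group = groups,
                         stringsAsFactors = FALSE))
}

#' Simulate a calibration dilution series
#'
#' Generates Cq values over a series of genomic DNA input masses for every
#' assay of a genotype, anchored so that the reference-gene Cq at 10 ng
#' equals `base_ref_cq`. With perfect amplification efficiency the Cq
#' decreases by exactly 1 cycle per two-fold mass increase; the slope of Cq
#' against log10 template copies is `-1 / log10(1 + efficiency)` (-3.3219
#' at efficiency 1). Template copies are derived from the input mass via
#' [copies_from_mass()]. Only well-level noise is applied.
#'
#' @param genotype An `rccx_genotype`.
#' @param noise An `rccx_noise_spec` (uses `base_ref_cq` and `well_sd`).
#' @param masses Input DNA masses in ng; all must be positive. Default
#'   `c(2.5, 5, 10, 20, 40, 80)`.
#' @param replicates Wells per mass. Default 3.
#' @param efficiency PCR amplification efficiency as a fraction (1 =
#'   perfect doubling per cycle). Default 1.
#' @return data.frame with columns `assay_id`, `channel`, `mass_ng`,
#'   `copies`, `replicate`, `cq`, `dropout`.
#' @export
simulate_dilution_series <- function(genotype, noise = noise_spec(),
                                     masses = c(2.5, 5, 10, 20, 40, 80),
                                     replicates = 3, efficiency = 1) {
  if (any(masses <= 0)) stop("all masses must be positive (ng)")
  stopifnot(efficiency > 0)
  slope <- -1 / log10(1 + efficiency)
  ref10 <- copies_from_mass(10, 2)
  grid <- expand.grid(assay_id = rccx_assays(), mass_ng = masses,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  build <- function(channel) {
    gcn <- if (channel == "reference") rep(2L, nrow(grid)) else
      genotype$gcn[grid$assay_id]
    copies <- ifelse(gcn >= 1,
                     copies_from_mass(grid$mass_ng, pmax(gcn, 1L)), 0)
    cq <- ifelse(gcn >= 1,
                 noise$base_ref_cq + slope * log10(copies / ref10) +
                   rnorm(nrow(grid), 0, noise$well_sd),
                 NA_real_)
    data.frame(assay_id = grid$assay_id, channel = channel,
               mass_ng = grid$mass_ng, copies = copies,
               replicate = grid$replicate, cq = cq,
               dropout = gcn < 1, stringsAsFactors = FALSE)
  }
  res <- rbind(build("reference"), build("target"))
  res <- res[order(res$assay_id, res$channel, res$mass_ng, res$replicate), ]
  rownames(res) <- NULL
  res
}
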