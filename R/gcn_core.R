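#' Measured GCN from a target/reference Cq pair
#'
#' The relative-quantification relation: since the reference gene is
#' present twice per diploid genome, a target with copy number `GCN`
#' satisfies `Cq(target) - Cq(reference) = 1 - log2(GCN)`. Inverting and
#' allowing a per-assay calibration offset (in cycles) gives
#' `GCN = 2 ^ (1 - (Cq_target - Cq_reference - offset))`. A dropout target
#' (absent Cq) maps to GCN 0; an absent reference Cq invalidates the
#' measurement.
#'
#' @param cq_target Target-channel Cq, cycles (NA = dropout).
#' @param cq_reference Reference-channel Cq, cycles.
#' @param offset Calibration offset, cycles. Default 0.
#' @return Measured GCN, a non-negative real number. Vectorised.
#' @examples
#' gcn_from_cq(26, 26)      # 2
#' gcn_from_cq(27, 26)      # 1
#' gcn_from_cq(25.415, 26)  # ~3
#' @export
gcn_from_cq <- function(cq_target, cq_reference, offset = 0) {
  if (any(is.na(cq_reference)))
    stop("absent reference Cq: measurement invalid")
  out <- 2^(1 - (cq_target - cq_reference - offset))
  out[is.na(cq_target)] <- 0
  out
}

#' Relative error of a measured GCN
#'
#' `(measured - integer) / integer`. Undefined (and disallowed) for
#' integer GCN 0: samples with zero copies have no relative scale.
#'
#' @param measured Measured GCN (real).
#' @param integer True integer GCN, must be >= 1.
#' @return Signed fraction. Vectorised.
#' @export
relative_error <- function(measured, integer) {
  if (any(integer < 1)) stop("relative error undefined for integer GCN 0")
  (measured - integer) / integer
}

#' Tune a calibration offset to zero mean relative error
#'
#' Finds the Cq-space offset `o` such that after applying it the mean
#' relative error of the calibration measurements is exactly zero. Because
#' applying an offset multiplies every measured GCN by `2^o`, the closed
#' form is `o = -log2(mean(measured / integer))`. Measurements with
#' integer GCN 0 are excluded (their relative error is undefined).
#'
#' @param measured Per-well measured GCNs.
#' @param integer Assigned integer GCNs, same length.
#' @return Offset in cycles (scalar).
#' @export
tune_offset <- function(measured, integer) {
  stopifnot(length(measured) == length(integer))
  keep <- integer >= 1 & !is.na(measured)
  if (!any(keep))
    stop("no measurement with integer GCN >= 1; cannot tune offset")
  -log2(mean(measured[keep] / integer[keep]))
}

#' Aggregate replicate well GCNs for one sample and assay
#'
#' Mean, SD (n-1 denominator), CV% and a normal-theory 95% confidence
#' interval of the mean, computed over non-dropout wells. A dropout well
#' carries measured GCN 0; zeros are excluded from the dispersion
#' statistics and counted separately. If every well dropped out the mean
#' is 0 and dispersion is undefined.
#'
#' @param wells Numeric vector of per-well measured GCNs (0 = dropout).
#' @return List with `mean`, `sd`, `cv_percent`, `ci95` (length-2), `n`
#'   (non-dropout wells), `n_dropout`, `all_dropout`.
#' @export
aggregate_replicates <- function(wells) {
  stopifnot(length(wells) >= 1, all(wells >= 0))
  keep <- wells > 0
  n_drop <- sum(!keep)
  x <- wells[keep]
  if (length(x) == 0)
    return(list(mean = 0, sd = NA_real_, cv_percent = NA_real_,
                ci95 = c(NA_real_, NA_real_), n = 0L,
                n_dropout = n_drop, all_dropout = TRUE))
  m <- mean(x)
  s <- if (length(x) >= 2) sd(x) else NA_real_
  ci <- if (length(x) >= 2)
    m + c(-1, 1) * qt(0.975, length(x) - 1) * s / sqrt(length(x))
  else c(NA_real_, NA_real_)
  list(mean = m, sd = s,
       cv_percent = if (is.na(s)) NA_real_ else 100 * s / m,
       ci95 = ci, n = length(x), n_dropout = n_drop, all_dropout = FALSE)
}

#' Classify a measured GCN as unambiguous or ambiguous
#'
#' A measured GCN within `halfwidth` (inclusive) of some non-negative
#' integer is unambiguous and assigned that integer; otherwise it is
#' ambiguous. With `halfwidth < 0.5` the assignment is unique. A small
#' numerical tolerance (1e-9) keeps boundary values such as 1.7 with a
#' half-width of 0.3 on the unambiguous side regardless of floating-point
#' representation.
#'
#' @param measured Measured GCN(s), >= 0.
#' @param halfwidth Unambiguous half-width in GCN units. Default 0.3.
#' @return data.frame with columns `measured`, `label` ("unambiguous" or
#'   "ambiguous") and `integer` (assigned integer, NA when ambiguous).
#' @export
classify_ambiguity <- function(measured, halfwidth = 0.3) {
  stopifnot(all(measured >= 0), halfwidth > 0, halfwidth < 0.5)
  nearest <- pmax(round(measured), 0)
  unamb <- abs(measured - nearest) <= halfwidth + 1e-9
  data.frame(measured = measured,
             label = ifelse(unamb, "unambiguous", "ambiguous"),
             integer = ifelse(unamb, nearest, NA_real_))
}

#' Expected GCNs from the genomic constraints
#'
#' The four totals observable from the seven assays (C4A + C4B, CYP21A1P +
#' CYP21A2, HERV deletion + insertion, breakpoint + 2) estimate the same
#' quantity, the total RCCX segment count. Their equal-weight mean is the
#' expected total; each locus' expected GCN is the expected total shared
#' between the paralog pair in proportion to the measured values, and the
#' expected breakpoint GCN is the expected total minus 2. A locus whose
#' measured value deviates from its expected value by more than
#' `flag_threshold` is flagged inconsistent. A pair summing to zero gets
#' expected 0 and no flag.
#'
#' @param measured Named numeric vector of the 7 per-sample mean measured
#'   GCNs (names = [rccx_assays()]).
#' @param flag_threshold Deviation above which a locus is flagged.
#'   Default 0.4.
#' @return List with `expected_total`, `totals` (the four total
#'   estimates), and `loci`: data.frame of `assay_id`, `measured`,
#'   `expected`, `deviation`, `inconsistent`.
#' @export
expected_gcn <- function(measured, flag_threshold = 0.4) {
  stopifnot(all(rccx_assays() %in% names(measured)))
  m <- measured[rccx_assays()]
  totals <- c(C4 = unname(m["C4A"] + m["C4B"]),
              CYP21 = unname(m["CYP21A1P"] + m["CYP21A2"]),
              HERV = unname(m["HERV_del"] + m["HERV_ins"]),
              BP = unname(m["BP"] + 2))
  et <- mean(totals)
  exp_locus <- setNames(numeric(7), rccx_assays())
  for (pair in rccx_pairs()) {
    s <- m[pair[1]] + m[pair[2]]
    if (s > 0) {
      exp_locus[pair[1]] <- et * m[pair[1]] / s
      exp_locus[pair[2]] <- et * m[pair[2]] / s
    }  # pair summing to 0: expected stays 0
  }
  exp_locus["BP"] <- max(et - 2, 0)
  dev <- abs(m - exp_locus)
  flag <- dev > flag_threshold
  for (pair in rccx_pairs())
    if (m[pair[1]] + m[pair[2]] == 0) flag[pair] <- FALSE
  loci <- data.frame(assay_id = rccx_assays(), measured = unname(m),
                     expected = unname(exp_locus), deviation = unname(dev),
                     inconsistent = unname(flag), stringsAsFactors = FALSE)
  list(expected_total = et, totals = totals, loci = loci)
}

#' Per-well and per-sample measured GCNs from a Cq table
#'
#' Pairs the target and reference channels of every well (duplex design:
#' the per-well GCN comes from same-well Cq values, and the sample mean is
#' the mean of per-well GCNs, not the GCN of mean Cqs), applies the
#' per-assay calibration offsets, and aggregates replicates per sample and
#' assay.
#'
#' @param cq Long-format Cq table as produced by [simulate_cq()] or
#'   [read_cq_table()].
#' @param config An `rccx_assay_config` carrying the offsets and ambiguity
#'   half-width.
#' @return List of class `rccx_measured` with `wells` (per-well GCNs) and
#'   `samples` (per sample x assay: mean, sd, cv_percent, ci, dropout
#'   counts, ambiguity label and assigned integer).
#' @export
measure_gcns <- function(cq, config = assay_config()) {
  check_assay_ids(cq$assay_id)
  tgt <- cq[cq$channel == "target", ]
  ref <- cq[cq$channel == "reference", ]
  key <- function(d) paste(d$sample_id, d$assay_id, d$run, d$replicate)
  idx <- match(key(tgt), key(ref))
  if (any(is.na(idx)))
    stop("target wells without a matching reference well: ",
         paste(head(key(tgt)[is.na(idx)], 3), collapse = "; "))
  wells <- data.frame(sample_id = tgt$sample_id, assay_id = tgt$assay_id,
                      run = tgt$run, replicate = tgt$replicate,
                      cq_target = tgt$cq, cq_reference = ref$cq[idx],
                      stringsAsFactors = FALSE)
  wells$gcn <- gcn_from_cq(wells$cq_target, wells$cq_reference,
                           config$offsets[wells$assay_id])
  wells$dropout <- is.na(wells$cq_target)
  grp <- split(wells, list(wells$sample_id, wells$assay_id), drop = TRUE)
  samples <- do.call(rbind, lapply(grp, function(w) {
    agg <- aggregate_replicates(w$gcn)
    data.frame(sample_id = w$sample_id[1], assay_id = w$assay_id[1],
               n_wells = agg$n, n_dropout = agg$n_dropout,
               mean = agg$mean, sd = agg$sd, cv_percent = agg$cv_percent,
               ci_lo = agg$ci95[1], ci_hi = agg$ci95[2],
               stringsAsFactors = FALSE)
  }))
  cls <- classify_ambiguity(samples$mean, config$ambiguity_halfwidth)
  samples$label <- cls$label
  samples$integer <- cls$integer
  samples <- samples[order(samples$sample_id, samples$assay_id), ]
  rownames(samples) <- NULL
  structure(list(wells = wells, samples = samples), class = "rccx_measured")
}

#' @export
print.rccx_measured <- function(x, ...) {
  cat("Measured GCNs:", nrow(x$wells), "wells,",
      length(unique(x$samples$sample_id)), "samples x",
      length(unique(x$samples$assay_id)), "assays\n")
  print(head(x$samples))
  invisible(x)
}

#' Wide per-sample measured-GCN matrix
#'
#' @param measured An `rccx_measured` object (or its `samples` component).
#' @return data.frame with `sample_id` and one column of mean measured GCN
#'   per assay.
#' @export
measured_wide <- function(measured) {
  s <- if (inherits(measured, "rccx_measured")) measured$samples else measured
  ids <- sort(unique(s$sample_id))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (a in rccx_assays()) {
    sub <- s[s$assay_id == a, ]
    out[[a]] <- sub$mean[match(ids, sub$sample_id)]
  }
  out
}

#' Tune per-assay calibration offsets on a cohort
#'
#' With known integer GCNs the offset of each assay is the closed-form
#' zero-mean-relative-error solution over all tuning wells (samples with
#' integer GCN 0 excluded). Without known integers an iterative scheme is
#' used: per-sample means are rounded to the nearest integer, offsets are
#' tuned against the rounding, GCNs are recomputed, and the loop repeats
#' until the assignments are stable (at most `max_iter` passes).
#'
#' @param cq Long-format Cq table.
#' @param truth Optional data.frame of known integer GCNs (`sample_id`
#'   plus one column per assay, as produced by [genotype_truth()]).
#' @param groups Optional data.frame (`sample_id`, `study_group`); when
#'   given, only "good" and "population" samples enter the tuning.
#' @param config Starting `rccx_assay_config`.
#' @param max_iter Maximum iterations of the round-tune-reround scheme.
#' @return An `rccx_assay_config` with tuned offsets.
#' @export
calibrate_offsets <- function(cq, truth = NULL, groups = NULL,
                              config = assay_config(), max_iter = 10) {
  if (!is.null(groups)) {
    keep <- groups$sample_id[groups$study_group %in% c("good", "population")]
    cq <- cq[cq$sample_id %in% keep, ]
  }
  offsets <- config$offsets
  if (!is.null(truth)) {
    meas <- measure_gcns(cq, assay_config(
      offsets, config$ambiguity_halfwidth, config$reference_gene))
    w <- meas$wells
    for (a in rccx_assays()) {
      wa <- w[w$assay_id == a, ]
      int <- truth[[a]][match(wa$sample_id, truth$sample_id)]
      ok <- !is.na(int) & int >= 1
      if (any(ok))
        offsets[a] <- offsets[a] + tune_offset(wa$gcn[ok], int[ok])
    }
    return(assay_config(offsets, config$ambiguity_halfwidth,
                        config$reference_gene))
  }
  prev <- NULL
  for (it in seq_len(max_iter)) {
    cfg <- assay_config(offsets, config$ambiguity_halfwidth,
                        config$reference_gene)
    meas <- measure_gcns(cq, cfg)
    assigned <- pmax(round(meas$samples$mean), 0)
    if (!is.null(prev) && identical(assigned, prev)) break
    prev <- assigned
    w <- meas$wells
    s <- meas$samples
    for (a in rccx_assays()) {
      wa <- w[w$assay_id == a, ]
      sa <- s[s$assay_id == a, ]
      int <- pmax(round(sa$mean), 0)[match(wa$sample_id, sa$sample_id)]
      ok <- int >= 1
      if (any(ok))
        offsets[a] <- offsets[a] + tune_offset(wa$gcn[ok], int[ok])
    }
  }
  assay_config(offsets, config$ambiguity_halfwidth, config$reference_gene)
}
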