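# Integer-GCN calling: two-stage LDA over the 7-assay measured-GCN vector
# with genomic-constraint consistency. Stage 1 estimates the total RCCX
# segment count from the four constraint totals; stage 2 splits each
# paralog pair conditional on the total.

# internal: the four total estimates from a wide measured-GCN frame
.constraint_totals <- function(w) {
  cbind(C4 = w$C4A + w$C4B,
        CYP21 = w$CYP21A1P + w$CYP21A2,
        HERV = w$HERV_del + w$HERV_ins,
        BP = w$BP + 2)
}

# internal: clamp a rounded paralog split to a fixed total
.round_pair <- function(a_measured, total) {
  a <- pmin(pmax(round(a_measured), 0), total)
  cbind(a = a, b = total - a)
}

# internal: named uniform priors for a label vector
.priors_for <- function(labels, mode) {
  if (mode == "empirical") return(NULL)
  cls <- sort(unique(labels))
  setNames(rep(1 / length(cls), length(cls)), cls)
}

#' Call integer GCNs for a cohort of measured-GCN vectors
#'
#' Two-stage linear discriminant estimation under the RCCX genomic
#' constraint (C4A + C4B = CYP21A1P + CYP21A2 = HERV deletion + insertion
#' = breakpoint + 2 = total segments):
#'
#' Stage 1 classifies the 4-vector of constraint totals into an integer
#' total `T`. Stage 2 resolves each paralog pair: if one paralog's
#' measured GCN is unambiguously 0 (within the ambiguity half-width of 0)
#' the pair is `(0, T)` by the zero-copy rule; otherwise an LDA on the
#' (pair, breakpoint) feature vector is evaluated with the admissible
#' classes restricted to splits summing to `T`. The breakpoint integer is
#' `T - 2`. Every emitted call satisfies the four-way constraint exactly.
#'
#' By default the cohort is its own reference set (self-training with
#' leave-one-out cross-validation); input classes are derived by rounding
#' unless `truth` supplies known integer GCNs. An external labelled
#' reference cohort can be given instead, in which case cross-validation
#' flags are not applicable to the new samples. Enriching the reference
#' set with rare-GCN samples improves the caller where class sizes are
#' small.
#'
#' A call is flagged ambiguous when any stage's (renormalised) posterior
#' falls below `posterior_threshold` or any applicable cross-validation
#' fails. `consistency_pass` records whether the rounded per-locus totals
#' of the sample all agree with the called total.
#'
#' @param measured Wide per-sample measured-GCN frame
#'   (see [measured_wide()]): `sample_id` plus the seven assay columns.
#' @param reference Optional wide measured-GCN frame used as the training
#'   set. Default: `measured` itself.
#' @param truth Optional known integer GCNs for the reference
#'   (`sample_id` plus assay columns, as from [genotype_truth()]).
#' @param posterior_threshold Minimum posterior for an unambiguous call.
#'   Default 0.95.
#' @param halfwidth Ambiguity half-width in GCN units. Default 0.3.
#' @param regularization Ridge scale for the LDA covariance. Default 1e-6.
#' @param priors One of "empirical" (class frequencies of the reference
#'   set) or "uniform".
#' @param use_breakpoint Include the measured breakpoint GCN as a stage-2
#'   feature. Default TRUE.
#' @return data.frame of integer calls: `sample_id`, `total`, the seven
#'   integer locus columns, `posterior` (minimum across stages),
#'   `cv_pass` (TRUE/FALSE/NA), `ambiguous`, `consistency_pass`.
#' @export
call_gcn <- function(measured, reference = NULL, truth = NULL,
                     posterior_threshold = 0.95, halfwidth = 0.3,
                     regularization = 1e-6,
                     priors = c("empirical", "uniform"),
                     use_breakpoint = TRUE) {
  priors <- match.arg(priors)
  need <- c("sample_id", rccx_assays())
  if (!all(need %in% names(measured)))
    stop("missing assay column(s): ",
         paste(setdiff(need, names(measured)), collapse = ", "))
  self <- is.null(reference)
  if (self) reference <- measured
  if (!all(need %in% names(reference)))
    stop("reference is missing assay column(s): ",
         paste(setdiff(need, names(reference)), collapse = ", "))
  if (anyNA(measured[rccx_assays()]) || anyNA(reference[rccx_assays()]))
    stop("measured GCNs must be present for all 7 assays (dropout = 0)")
  n <- nrow(measured)
  tm <- .constraint_totals(measured)
  tr <- .constraint_totals(reference)

  # --- reference input classes -------------------------------------------
  if (!is.null(truth)) {
    idx <- match(reference$sample_id, truth$sample_id)
    if (anyNA(idx)) stop("truth is missing reference sample(s)")
    tot_lab <- truth$C4A[idx] + truth$C4B[idx]
    pair_ref <- lapply(rccx_pairs(), function(p)
      cbind(a = truth[[p[1]]][idx], b = truth[[p[2]]][idx]))
  } else {
    tot_lab <- pmax(round(rowMeans(tr)), 2)
    pair_ref <- lapply(rccx_pairs(), function(p)
      .round_pair(reference[[p[1]]], tot_lab))
  }

  # --- stage 1: total segment count --------------------------------------
  if (length(unique(tot_lab)) >= 2) {
    m1 <- train_lda(tr, tot_lab, .priors_for(tot_lab, priors),
                    regularization)
    c1 <- classify_lda(m1, tm)
    total <- as.integer(c1$class)
    p1 <- c1$posterior[cbind(seq_len(n), match(c1$class, m1$classes))]
    cv1 <- if (self)
      loo_cross_validate(tr, tot_lab, .priors_for(tot_lab, priors),
                         regularization)
    else rep("not_applicable", n)
  } else {
    total <- rep(as.integer(tot_lab[1]), n)
    p1 <- rep(1, n)
    cv1 <- rep("not_applicable", n)
  }

  # --- stage 2: paralog pair splits ---------------------------------------
  ints <- matrix(NA_integer_, n, 7,
                 dimnames = list(NULL, rccx_assays()))
  ints[, "BP"] <- total - 2L
  post_min <- p1
  cv_fail <- cv1 == "fail"
  cv_any <- cv1 == "pass" | cv_fail
  fallback <- rep(FALSE, n)

  for (pn in names(rccx_pairs())) {
    p <- rccx_pairs()[[pn]]
    lab <- paste(pair_ref[[pn]][, "a"], pair_ref[[pn]][, "b"], sep = "/")
    feat_cols <- if (use_breakpoint) c(p, "BP") else p
    fr <- as.matrix(reference[feat_cols])
    fm <- as.matrix(measured[feat_cols])
    model <- if (length(unique(lab)) >= 2)
      tryCatch(train_lda(fr, lab, .priors_for(lab, priors), regularization),
               error = function(e) NULL)
    else NULL
    cvp <- if (self && !is.null(model))
      loo_cross_validate(fr, lab, .priors_for(lab, priors), regularization)
    else rep("not_applicable", n)
    pred <- if (!is.null(model)) classify_lda(model, fm) else NULL
    sums <- if (!is.null(model))
      vapply(strsplit(model$classes, "/"),
             function(s) sum(as.integer(s)), integer(1))
    else integer(0)

    for (i in seq_len(n)) {
      ma <- measured[[p[1]]][i]; mb <- measured[[p[2]]][i]
      ti <- total[i]
      zero_a <- ma <= halfwidth + 1e-9
      zero_b <- mb <= halfwidth + 1e-9
      if (zero_a || zero_b) {
        # zero-copy rule: the non-zero paralog carries the whole total
        if (zero_a && zero_b) {
          ab <- if (mb >= ma) c(0L, ti) else c(ti, 0L)
        } else if (zero_a) ab <- c(0L, ti) else ab <- c(ti, 0L)
        ints[i, p] <- ab
        next
      }
      adm <- which(sums == ti)
      if (!is.null(pred) && length(adm)) {
        pr <- pred$posterior[i, adm]
        j <- adm[which.max(pr)]
        ab <- as.integer(strsplit(model$classes[j], "/")[[1]])
        ints[i, p] <- ab
        post_min[i] <- min(post_min[i], max(pr) / sum(pr))
        if (cvp[i] == "fail") cv_fail[i] <- TRUE
        if (cvp[i] != "not_applicable") cv_any[i] <- TRUE
      } else {
        ab <- .round_pair(ma, ti)[1, ]
        ints[i, p] <- as.integer(ab)
        fallback[i] <- TRUE
      }
    }
  }

  # --- consistency of rounded per-locus totals with the called total -----
  cons <- vapply(seq_len(n), function(i) {
    r <- round(unlist(measured[i, rccx_assays()]))
    all(c(r["C4A"] + r["C4B"], r["CYP21A1P"] + r["CYP21A2"],
          r["HERV_del"] + r["HERV_ins"], r["BP"] + 2) == total[i])
  }, logical(1))

  out <- data.frame(sample_id = measured$sample_id, total = total,
                    ints, stringsAsFactors = FALSE)
  out$posterior <- post_min
  out$cv_pass <- ifelse(cv_fail, FALSE, ifelse(cv_any, TRUE, NA))
  out$ambiguous <- post_min < posterior_threshold | cv_fail | fallback
  out$consistency_pass <- cons
  # hard invariant: every call satisfies the four-way constraint exactly
  stopifnot(out$C4A + out$C4B == out$total,
            out$CYP21A1P + out$CYP21A2 == out$total,
            out$HERV_del + out$HERV_ins == out$total,
            out$BP + 2L == out$total,
            out[rccx_assays()] >= 0)
  rownames(out) <- NULL
  out
}

#' Call integer GCNs for a single sample against a reference set
#'
#' Convenience wrapper around [call_gcn()] for one 7-assay measured-GCN
#' vector classified against a labelled (or self-rounded) reference
#' cohort.
#'
#' @param measured Named numeric vector of the 7 measured GCNs.
#' @param reference Wide measured-GCN frame of the reference cohort.
#' @param truth Optional integer GCNs for the reference samples.
#' @param sample_id Identifier for the new sample.
#' @param ... Passed on to [call_gcn()].
#' @return One-row data.frame of the integer call.
#' @export
call_sample <- function(measured, reference, truth = NULL,
                        sample_id = "sample", ...) {
  stopifnot(all(rccx_assays() %in% names(measured)))
  row <- data.frame(sample_id = sample_id,
                    as.list(measured[rccx_assays()]),
                    stringsAsFactors = FALSE)
  call_gcn(row, reference = reference, truth = truth, ...)
}
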