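#' Template copies from genomic DNA mass
#'
#' Converts an input mass of human genomic DNA to the number of template
#' copies of a locus. One diploid genome weighs
#' `2 * haploid_bp * bp_mass / N_A` grams (about 6.7 pg with the defaults:
#' 3.1 Gbp haploid genome, 650 g/mol per base pair).
#'
#' @param mass_ng Input DNA mass in nanograms; must be positive.
#' @param copies_per_diploid Copies of the locus per diploid genome.
#'   Default 1.
#' @param haploid_bp Haploid genome size in base pairs. Default 3.1e9.
#' @param bp_mass Average molar mass of a base pair, g/mol. Default 650.
#' @param avogadro Avogadro's number. Default 6.02214076e23.
#' @return Number of template copies (real). Vectorised in `mass_ng` and
#'   `copies_per_diploid`.
#' @examples
#' copies_from_mass(2.5)      # ~374 copies of a single-copy locus
#' @export
copies_from_mass <- function(mass_ng, copies_per_diploid = 1,
                             haploid_bp = 3.1e9, bp_mass = 650,
                             avogadro = 6.02214076e23) {
  if (any(mass_ng <= 0)) stop("mass must be positive (ng)")
  genome_g <- 2 * haploid_bp * bp_mass / avogadro
  (mass_ng * 1e-9) / genome_g * copies_per_diploid
}

#' Fit a qPCR calibration (standard) curve
#'
#' Ordinary least squares of Cq on log10 template copies. The
#' amplification efficiency follows the convention
#' `E = 10^(-1/slope) - 1`, so a perfect-doubling slope of -3.3219 gives
#' E = 1 (100%). A non-negative slope yields a fit flagged `degenerate`
#' with a warning rather than an error.
#'
#' @param copies Template copies per reaction (> 0).
#' @param cq Observed Cq values, same length.
#' @return Object of class `rccx_calfit`: list with `slope`, `intercept`,
#'   `efficiency`, `r2`, `residual_sd`, `n`, `degenerate`, `fit` (the lm),
#'   and the input data.
#' @export
fit_calibration <- function(copies, cq) {
  stopifnot(length(copies) == length(cq), all(copies > 0))
  keep <- !is.na(cq)
  copies <- copies[keep]; cq <- cq[keep]
  if (length(unique(copies)) < 3)
    stop("need at least 3 distinct concentrations")
  x <- log10(copies)
  fit <- lm(cq ~ x)
  slope <- unname(coef(fit)[2])
  degenerate <- !is.finite(slope) || slope >= 0 ||
    isTRUE(all.equal(sd(cq), 0))
  if (degenerate)
    warning("degenerate calibration fit (non-negative or undefined slope)")
  eff <- if (degenerate) NA_real_ else 10^(-1 / slope) - 1
  rss <- sum(residuals(fit)^2)
  tss <- sum((cq - mean(cq))^2)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 efficiency = eff,
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 residual_sd = sqrt(rss / max(length(cq) - 2, 1)),
                 n = length(cq), degenerate = degenerate, fit = fit,
                 copies = copies, cq = cq),
            class = "rccx_calfit")
}

#' @export
print.rccx_calfit <- function(x, ...) {
  cat(sprintf(
    "Calibration fit: slope %.4f, efficiency %.4f, R2 %.5f, n = %d%s\n",
    x$slope, x$efficiency, x$r2, x$n,
    if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Hubaux-Vos limit of detection from a calibration series
#'
#' The Hubaux-Vos construction assumes a response linear in concentration,
#' so the Cq values are linearised to `y = 2^(-Cq)` (proportional to
#' starting template under ideal amplification) and regressed on copies.
#' The decision limit is the upper one-sided `1 - alpha` prediction bound
#' of the regression at zero concentration; the LOD is the smallest
#' concentration whose lower one-sided `1 - beta` prediction bound exceeds
#' the decision limit. Both bounds use the t distribution with n - 2
#' degrees of freedom. Deterministic given the data.
#'
#' @param copies Template copies per reaction.
#' @param cq Observed Cq values, same length.
#' @param alpha False-positive rate, in (0, 0.5). Default 0.05.
#' @param beta False-negative rate, in (0, 0.5). Default 0.05.
#' @return Object of class `rccx_lod`: list with `lod_copies`, `alpha`,
#'   `beta`, `decision_limit`, and the linearised regression summary.
#' @export
lod_hubaux_vos <- function(copies, cq, alpha = 0.05, beta = 0.05) {
  stopifnot(alpha > 0, alpha < 0.5, beta > 0, beta < 0.5,
            length(copies) == length(cq))
  keep <- !is.na(cq)
  x <- copies[keep]; y <- 2^(-cq[keep])
  n <- length(x)
  if (length(unique(x)) < 3) stop("need at least 3 distinct concentrations")
  fit <- lm(y ~ x)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  s <- sqrt(sum(residuals(fit)^2) / (n - 2))
  if (!is.finite(b) || b <= 0 || s <= 0)
    stop("degenerate linearised fit: slope must be positive with ",
         "positive residual SD")
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  se <- function(x0) s * sqrt(1 + 1 / n + (x0 - xbar)^2 / sxx)
  yc <- a + qt(1 - alpha, n - 2) * se(0)
  f <- function(x0) a + b * x0 - qt(1 - beta, n - 2) * se(x0) - yc
  hi <- max(x) * 10
  if (f(hi) <= 0) stop("LOD exceeds the calibrated range")
  lod <- uniroot(f, c(0, hi), tol = 1e-12)$root
  structure(list(lod_copies = lod, alpha = alpha, beta = beta,
                 decision_limit = yc, intercept = a, slope = b,
                 residual_sd = s, n = n),
            class = "rccx_lod")
}

#' @export
print.rccx_lod <- function(x, ...) {
  cat(sprintf("Hubaux-Vos LOD: %.1f copies (alpha %.3g, beta %.3g)\n",
              x$lod_copies, x$alpha, x$beta))
  invisible(x)
}

#' Pooled coefficient of variation
#'
#' Degrees-of-freedom-weighted root-mean-square of per-group CVs:
#' `sqrt(sum((n_g - 1) CV_g^2) / sum(n_g - 1)) * 100`. Groups with fewer
#' than two values or a non-positive mean are excluded with a warning.
#'
#' @param groups List of numeric vectors, one per replicate group.
#' @return Pooled CV as a percentage (scalar).
#' @export
pooled_cv <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  cv2 <- df <- numeric(0)
  for (g in groups) {
    g <- g[!is.na(g)]
    if (length(g) < 2) next
    m <- mean(g)
    if (m <= 0) {
      warning("group with non-positive mean excluded from pooled CV")
      next
    }
    cv2 <- c(cv2, (sd(g) / m)^2)
    df <- c(df, length(g) - 1)
  }
  if (!length(df)) stop("no usable group (need >= 2 values, positive mean)")
  100 * sqrt(sum(df * cv2) / sum(df))
}

#' Normalised root-mean-square error of target-Cq tracking
#'
#' Measures how efficiently the target-gene Cq follows the reference-gene
#' Cq across wells of a sample. The predicted target Cq of well i is
#' `reference Cq_i + offset + 1 - log2(integer GCN)`; the NRMSE is the
#' root-mean-square of observed minus predicted, normalised by the mean
#' observed target Cq. Adding a constant to both channels leaves the
#' numerator unchanged.
#'
#' @param target_cq Observed target Cq values.
#' @param reference_cq Paired reference Cq values, same length.
#' @param integer_gcn The sample's integer GCN at this locus, >= 1.
#' @param offset Calibration offset of the assay, cycles. Default 0.
#' @return NRMSE as a dimensionless fraction.
#' @export
nrmse <- function(target_cq, reference_cq, integer_gcn, offset = 0) {
  stopifnot(length(target_cq) == length(reference_cq))
  if (integer_gcn < 1) stop("NRMSE undefined for integer GCN 0")
  keep <- !is.na(target_cq) & !is.na(reference_cq)
  obs <- target_cq[keep]
  pred <- reference_cq[keep] + offset + 1 - log2(integer_gcn)
  sqrt(mean((obs - pred)^2)) / mean(obs)
}

#' Pooled Cq precision report
#'
#' Pooled CV% of raw Cq values per assay and channel, at two scopes:
#' repeatability (replicate wells within a run) and reproducibility
#' (all wells of a sample across runs).
#'
#' @param cq Long-format Cq table.
#' @return data.frame with `assay_id`, `channel`, `scope`,
#'   `pooled_cv_percent`.
#' @export
precision_report <- function(cq) {
  cq <- cq[!is.na(cq$cq), ]
  out <- list()
  for (a in unique(cq$assay_id)) for (ch in unique(cq$channel)) {
    sub <- cq[cq$assay_id == a & cq$channel == ch, ]
    if (!nrow(sub)) next
    rep_groups <- split(sub$cq, paste(sub$sample_id, sub$run))
    rpd_groups <- split(sub$cq, sub$sample_id)
    for (sc in c("repeatability", "reproducibility")) {
      g <- if (sc == "repeatability") rep_groups else rpd_groups
      out[[length(out) + 1]] <- data.frame(
        assay_id = a, channel = ch, scope = sc,
        pooled_cv_percent = tryCatch(pooled_cv(g), error = function(e) NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample NRMSE report
#'
#' @param cq Long-format Cq table.
#' @param truth Integer GCN table (`sample_id` plus assay columns).
#' @param config An `rccx_assay_config` (offsets used in the prediction).
#' @return data.frame with `sample_id`, `assay_id`, `nrmse`; samples with
#'   integer GCN 0 at a locus are excluded there.
#' @export
nrmse_report <- function(cq, truth, config = assay_config()) {
  m <- measure_gcns(cq, config)
  w <- m$wells
  out <- list()
  for (a in rccx_assays()) {
    wa <- w[w$assay_id == a & !w$dropout, ]
    if (!nrow(wa)) next
    for (sid in unique(wa$sample_id)) {
      n_int <- truth[[a]][match(sid, truth$sample_id)]
      if (is.na(n_int) || n_int < 1) next
      ws <- wa[wa$sample_id == sid, ]
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid, assay_id = a,
        nrmse = nrmse(ws$cq_target, ws$cq_reference, n_int,
                      config$offsets[[a]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
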