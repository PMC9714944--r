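#' Normal relative-error model of a qPCR assay
#'
#' The per-sample average relative error of measured GCNs is modelled as
#' `X ~ Normal(mu, sigma^2)`. A measurement of a sample with integer GCN
#' `n` is then `n * (1 + X)` on the measured-GCN axis, so the ±0.3
#' unambiguous window and the 0.7 misclassification boundary around the
#' integers translate into windows of width `0.3/n` and `0.7/n` on the
#' relative-error axis. All rates are invariant under `mu -> -mu`.
#'
#' @param mu Signed mean relative error (fraction).
#' @param sigma SD of the relative error (fraction), > 0.
#' @return Object of class `rccx_error_model`.
#' @export
error_model <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "rccx_error_model")
}

#' @export
print.rccx_error_model <- function(x, ...) {
  cat(sprintf("Normal relative-error model: mu = %.4f, sigma = %.4f\n",
              x$mu, x$sigma))
  invisible(x)
}

# internal: P(|X| < c) for X ~ N(mu, sigma^2)
.p_abs_below <- function(c, mu, sigma) {
  pnorm((c - mu) / sigma) - pnorm((-c - mu) / sigma)
}

#' Ambiguity and misclassification rates at an integer GCN
#'
#' Closed-form rates under the normal relative-error model. With boundary
#' `b = 1 - halfwidth`:
#' ambiguity = P(halfwidth/n < |X| < b/n), the measurement lands between
#' the unambiguous windows of `n` and a neighbour; misclassification =
#' P(|X| >= b/n), it lands inside a wrong integer's window. The remainder,
#' 100 - ambiguity - misclassification, is the unambiguous rate.
#'
#' @param model An `rccx_error_model`.
#' @param n Integer GCN, >= 1. Vectorised.
#' @param halfwidth Unambiguous half-width in GCN units. Default 0.3.
#' @return data.frame with columns `n`, `ambiguity`, `misclassification`
#'   (percent).
#' @export
rate_at_gcn <- function(model, n, halfwidth = 0.3) {
  stopifnot(inherits(model, "rccx_error_model"), all(n >= 1),
            halfwidth > 0, halfwidth < 0.5)
  b <- 1 - halfwidth
  inner <- .p_abs_below(halfwidth / n, model$mu, model$sigma)
  outer <- .p_abs_below(b / n, model$mu, model$sigma)
  data.frame(n = n,
             ambiguity = 100 * (outer - inner),
             misclassification = 100 * (1 - outer))
}

#' Fit a normal relative-error model to two observed ambiguity rates
#'
#' Solves the 2x2 system `ambiguity(model, n_i) = rate_i` for
#' `(|mu|, sigma)` by deterministic multi-start Nelder-Mead least squares
#' over the bounded box `|mu| in [0, 0.5]`, `sigma in (1e-6, 0.5]`. The
#' ambiguity rate is not monotone in `mu`, so a bracketing scheme is
#' unreliable; the multi-start search is exhaustive over a fixed grid of
#' starting points and involves no randomness. Only `|mu|` is
#' identifiable (rates are symmetric in the sign of `mu`).
#'
#' @param n Two distinct integer GCNs.
#' @param ambiguity Observed ambiguity rates at those GCNs, percent, each
#'   in (0, 100).
#' @param halfwidth Unambiguous half-width. Default 0.3.
#' @param tol Maximum allowed residual per equation, in probability units.
#'   Default 1e-10.
#' @return An `rccx_error_model` with `mu = |mu|`.
#' @export
fit_error_model <- function(n, ambiguity, halfwidth = 0.3, tol = 1e-10) {
  stopifnot(length(n) == 2, length(ambiguity) == 2, n[1] != n[2],
            all(ambiguity > 0), all(ambiguity < 100))
  target <- ambiguity / 100
  b <- 1 - halfwidth
  amb <- function(mu, s, k)
    .p_abs_below(b / k, mu, s) - .p_abs_below(halfwidth / k, mu, s)
  obj <- function(p) {
    mu <- p[1]; s <- p[2]
    if (mu < 0 || mu > 0.5 || s < 1e-6 || s > 0.5) return(1e6)
    (amb(mu, s, n[1]) - target[1])^2 + (amb(mu, s, n[2]) - target[2])^2
  }
  best <- NULL
  for (mu0 in seq(0, 0.45, by = 0.05)) {
    for (s0 in seq(0.02, 0.45, by = 0.05)) {
      o <- optim(c(mu0, s0), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-16, maxit = 5000))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  # polish to machine precision with a damped Gauss-Newton
  # (Levenberg-Marquardt) iteration; the damping keeps the step defined
  # when mu sits on the symmetric boundary mu = 0, where the Jacobian
  # column for mu vanishes
  clamp <- function(p) pmin(pmax(p, c(0, 1e-6)), c(0.5, 0.5))
  p <- clamp(best$par)
  F <- function(p) c(amb(p[1], p[2], n[1]) - target[1],
                     amb(p[1], p[2], n[2]) - target[2])
  lam <- 1e-8
  for (it in 1:200) {
    f0 <- F(p)
    if (max(abs(f0)) < 1e-14) break
    h <- 1e-7
    J <- cbind((F(clamp(p + c(h, 0))) - f0) / h,
               (F(clamp(p + c(0, h))) - f0) / h)
    A <- crossprod(J)
    g <- drop(t(J) %*% f0)
    improved <- FALSE
    for (k in 1:30) {
      step <- tryCatch(solve(A + lam * diag(2), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- clamp(p - step)
        if (sum(F(cand)^2) < sum(f0^2)) {
          p <- cand
          lam <- max(lam / 10, 1e-12)
          improved <- TRUE
          break
        }
      }
      lam <- lam * 10
    }
    if (!improved) break
  }
  mu <- abs(p[1]); s <- p[2]
  resid <- sqrt(c((amb(mu, s, n[1]) - target[1])^2,
                  (amb(mu, s, n[2]) - target[2])^2))
  if (any(resid > tol)) {
    # near the symmetric boundary the rates depend on mu only to second
    # order and the 2-D iteration loses precision; try the exact mu = 0
    # solution by 1-D root finding in sigma
    g1 <- function(s) amb(0, s, n[1]) - target[1]
    sgrid <- seq(1e-6, 0.5, length.out = 2001)
    v <- vapply(sgrid, g1, numeric(1))
    for (j in which(diff(sign(v)) != 0)) {
      s0 <- uniroot(g1, sgrid[c(j, j + 1)], tol = 1e-15)$root
      if (abs(amb(0, s0, n[2]) - target[2]) <= tol) {
        mu <- 0; s <- s0
        resid <- abs(c(g1(s0), amb(0, s0, n[2]) - target[2]))
        break
      }
    }
  }
  if (any(resid > tol))
    stop(sprintf(
      "no (|mu|, sigma) in bounds reproduces the rates (residual %.2e)",
      max(resid)))
  error_model(mu, s)
}

#' Rate table over a grid of assays and integer GCNs
#'
#' Builds the numeric grid of ambiguity and misclassification rates for a
#' set of per-assay error models, with an optional per-GCN variant when
#' models were fitted per GCN class.
#'
#' @param models Named list of `rccx_error_model`, one per assay.
#' @param n Integer GCNs to tabulate. Default 1:4.
#' @param halfwidth Unambiguous half-width. Default 0.3.
#' @return data.frame with `assay_id`, `n`, `ambiguity`,
#'   `misclassification` (percent).
#' @export
rate_table <- function(models, n = 1:4, halfwidth = 0.3) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  out <- do.call(rbind, lapply(names(models), function(a) {
    r <- rate_at_gcn(models[[a]], n, halfwidth)
    cbind(assay_id = a, r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format a rate table for display
#'
#' Rates are printed to two decimals; cells below `sub_threshold` percent
#' are rendered with a sub-threshold symbol ("<0.01%" by default; setting
#' `literal = TRUE` reproduces the inverted ">0.01%" convention some
#' published tables use for the same cells).
#'
#' @param table Numeric rate table from [rate_table()].
#' @param sub_threshold Threshold in percent below which the symbol is
#'   used. Default 0.005.
#' @param literal Use ">0.01%" instead of "<0.01%". Default FALSE.
#' @return data.frame of formatted character cells.
#' @export
format_rate_table <- function(table, sub_threshold = 0.005,
                              literal = FALSE) {
  symbol <- if (literal) ">0.01%" else "<0.01%"
  fmt <- function(x) ifelse(x < sub_threshold, symbol,
                            sprintf("%.2f%%", x))
  data.frame(assay_id = table$assay_id, n = table$n,
             ambiguity = fmt(table$ambiguity),
             misclassification = fmt(table$misclassification),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo check of the closed-form rates
#'
#' Estimates the ambiguity and misclassification rates at an integer GCN
#' by direct simulation of measured GCNs `n * (1 + X)` and the ±halfwidth
#' window geometry on the measured axis (the nearest-integer rule, which
#' also covers wrap-around into windows beyond the adjacent integers).
#' Used as the independent oracle for [rate_at_gcn()].
#'
#' @param model An `rccx_error_model`.
#' @param n Integer GCN.
#' @param draws Number of Monte-Carlo draws. Default 1e6.
#' @param halfwidth Unambiguous half-width. Default 0.3.
#' @return List with `ambiguity`, `misclassification` (percent) and their
#'   binomial standard errors (`se_ambiguity`, `se_misclassification`).
#' @export
mc_rate_at_gcn <- function(model, n, draws = 1e6, halfwidth = 0.3) {
  x <- rnorm(draws, model$mu, model$sigma)
  m <- n * (1 + x)
  nearest <- pmax(round(m), 0)
  unamb <- abs(m - nearest) <= halfwidth
  amb <- mean(!unamb)
  mis <- mean(unamb & nearest != n)
  list(ambiguity = 100 * amb, misclassification = 100 * mis,
       se_ambiguity = 100 * sqrt(amb * (1 - amb) / draws),
       se_misclassification = 100 * sqrt(mis * (1 - mis) / draws))
}
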