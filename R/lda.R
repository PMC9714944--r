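#' Train a linear discriminant analysis model
#'
#' From-scratch LDA: per-class means, pooled within-class covariance with
#' an `N - K` denominator, and a ridge term `regularization * trace/d` on
#' the diagonal to keep the covariance invertible on small reference sets.
#' If the pooled covariance has zero trace (e.g. exactly replicated
#' feature vectors), the absolute ridge `regularization * I` is used so
#' degenerate but separable training sets still classify correctly.
#' Priors default to the empirical class frequencies.
#'
#' @param x Numeric matrix (or data.frame) of feature vectors, one row per
#'   sample.
#' @param labels Class labels, one per row.
#' @param priors Optional named numeric vector of class priors (must sum
#'   to 1). Default: empirical frequencies.
#' @param regularization Ridge scale. Default 1e-6.
#' @return Object of class `rccx_lda`: list with `classes`, `means`,
#'   `cov`, `cov_inv`, `priors`, `counts`, `regularization`.
#' @export
train_lda <- function(x, labels, priors = NULL, regularization = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("features must be finite")
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  d <- ncol(x); n <- nrow(x); k <- length(classes)
  if (n - k < 1)
    stop("no residual degrees of freedom for the pooled covariance ",
         "(every class is a singleton)")
  counts <- table(factor(labels, levels = classes))
  means <- matrix(0, k, d, dimnames = list(classes, colnames(x)))
  for (cl in classes)
    means[cl, ] <- colMeans(x[labels == cl, , drop = FALSE])
  S <- matrix(0, d, d)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, means[cl, ])
    S <- S + crossprod(xc)
  }
  sigma <- S / (n - k)
  ridge <- regularization * sum(diag(sigma)) / d
  if (ridge <= 0) ridge <- regularization
  sigma_r <- sigma + diag(ridge, d)
  inv <- tryCatch(solve(sigma_r), error = function(e)
    stop("pooled covariance singular after regularization; ",
         "increase `regularization`"))
  if (is.null(priors)) {
    priors <- as.numeric(counts) / n
    names(priors) <- classes
  } else {
    if (is.null(names(priors)) || !all(classes %in% names(priors)))
      stop("`priors` must be named by class")
    priors <- priors[classes]
    if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1")
  }
  structure(list(classes = classes, means = means, cov = sigma_r,
                 cov_inv = inv, priors = priors,
                 counts = as.integer(counts) |> setNames(classes),
                 regularization = regularization),
            class = "rccx_lda")
}

#' @export
print.rccx_lda <- function(x, ...) {
  cat("LDA model:", length(x$classes), "classes,",
      ncol(x$means), "features\n")
  print(data.frame(class = x$classes, n = as.integer(x$counts),
                   prior = round(as.numeric(x$priors), 4)))
  invisible(x)
}

#' Classify feature vectors with a trained LDA model
#'
#' Linear discriminant score of class k:
#' `delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log(prior_k)`.
#' The predicted class is the argmax; posteriors are the softmax of the
#' scores (computed with max subtraction, so they sum to 1 to machine
#' precision).
#'
#' @param model An `rccx_lda`.
#' @param x Matrix (or vector) of feature rows to classify.
#' @return List with `class` (character vector) and `posterior`
#'   (matrix, one row per input, columns named by class).
#' @export
classify_lda <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  if (ncol(x) != ncol(model$means))
    stop("feature dimension mismatch: model has ", ncol(model$means))
  A <- model$cov_inv %*% t(model$means)            # d x K
  quad <- 0.5 * colSums(t(model$means) * A)        # K
  delta <- x %*% A - matrix(quad, nrow(x), length(quad), byrow = TRUE) +
    matrix(log(model$priors), nrow(x), length(quad), byrow = TRUE)
  shift <- delta - apply(delta, 1, max)
  post <- exp(shift) / rowSums(exp(shift))
  colnames(post) <- model$classes
  list(class = model$classes[max.col(delta, ties.method = "first")],
       posterior = post)
}

#' Leave-one-out cross-validation of an LDA classification
#'
#' For every sample whose class has at least two members, the model is
#' retrained without that sample (empirical priors recomputed unless
#' fixed priors are supplied) and the held-out sample is classified; it
#' passes when the predicted class equals its input class. Samples in
#' singleton classes cannot be cross-validated and are reported
#' `not_applicable`.
#'
#' @inheritParams train_lda
#' @return Character vector, one of `"pass"`, `"fail"`,
#'   `"not_applicable"` per sample.
#' @export
loo_cross_validate <- function(x, labels, priors = NULL,
                               regularization = 1e-6) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  counts <- table(labels)
  vapply(seq_len(nrow(x)), function(i) {
    if (counts[[labels[i]]] < 2) return("not_applicable")
    m <- tryCatch(
      train_lda(x[-i, , drop = FALSE], labels[-i], priors, regularization),
      error = function(e) NULL)
    if (is.null(m)) return("not_applicable")
    pred <- classify_lda(m, x[i, , drop = FALSE])$class
    if (pred == labels[i]) "pass" else "fail"
  }, character(1))
}
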