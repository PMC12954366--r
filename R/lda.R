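#' Fit a pooled-covariance linear discriminant classifier
#'
#' Gaussian equal-covariance LDA: per-class means, a pooled within-class
#' covariance (pseudo-inverted by eigendecomposition when rank
#' deficient), empirical class priors, and the linear discriminant
#' `delta_c(x) = x' S+ mu_c - mu_c' S+ mu_c / 2 + log pi_c`. Prediction
#' is the argmax over classes, with ties broken in favour of the
#' earliest class level. No shrinkage is applied by default; a
#' Ledoit-Wolf style convex shrinkage towards the scaled identity is
#' available through `shrinkage`.
#'
#' @param x numeric matrix, samples x features.
#' @param y class labels (coerced to factor; level order defines the
#'   tie-break order).
#' @param shrinkage shrinkage intensity in `[0, 1]` towards
#'   `mean(diag(S)) * I`; 0 disables it.
#' @return An object of class `lda_model` with elements `means`,
#'   `cov`, `priors`, `weights` (features x classes), `intercepts`,
#'   and `classes`.
#' @export
fit_lda <- function(x, y, shrinkage = 0) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) abort("Need at least 2 classes.")
  counts <- table(y)
  if (any(counts < 2L)) {
    abort(sprintf("Every class needs at least 2 samples (got %s).",
                  paste(sprintf("%s=%d", names(counts), counts),
                        collapse = ", ")))
  }
  n <- nrow(x)
  p <- ncol(x)
  k <- length(classes)
  means <- matrix(0, k, p, dimnames = list(classes, colnames(x)))
  for (cl in classes) means[cl, ] <- colMeans(x[y == cl, , drop = FALSE])
  s <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2, means[cl, ], `-`)
    s <- s + crossprod(xc)
  }
  s <- s / (n - k)
  if (shrinkage > 0) {
    s <- (1 - shrinkage) * s + shrinkage * mean(diag(s)) * diag(p)
  }
  eg <- eigen(s, symmetric = TRUE)
  tol <- max(eg$values[1], 0) * p * .Machine$double.eps
  pos <- eg$values > tol
  if (!all(pos)) {
    warn(sprintf(
      "Pooled covariance is rank deficient (rank %d of %d); using its pseudo-inverse.",
      sum(pos), p))
  }
  if (!any(pos)) {
    s_inv <- matrix(0, p, p)
  } else {
    v <- eg$vectors[, pos, drop = FALSE]
    s_inv <- v %*% (t(v) / eg$values[pos])
  }
  priors <- as.numeric(counts) / n
  w <- s_inv %*% t(means) # features x classes
  b <- -0.5 * colSums(t(means) * w) + log(priors)
  structure(list(means = means, cov = s, priors = priors, weights = w,
                 intercepts = b, classes = classes),
            class = "lda_model")
}

#' Predict classes from a fitted LDA model
#'
#' @param object an `lda_model`.
#' @param newdata numeric matrix, samples x features.
#' @param type `"class"` (default) for labels, `"score"` for the matrix
#'   of discriminant values.
#' @param ... unused.
#' @return Character vector of predicted labels, or a score matrix.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  scores <- as.matrix(newdata) %*% object$weights
  scores <- sweep(scores, 2, object$intercepts, `+`)
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  object$classes[apply(scores, 1, which.max)]
}
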