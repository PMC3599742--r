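#' Fit the Gaussian naive Bayes reference model
#'
#' Per-class prior = class frequency in the training data; per-feature,
#' per-class Gaussian with maximum-likelihood mean and variance. Variances
#' are floored at `var_floor_frac` times the largest pooled (whole training
#' set) feature variance so that features constant within a class — common
#' with sparse gram probabilities — keep a finite log-density; if all
#' features are constant the floor itself is used.
#'
#' @param x Numeric feature matrix (rows = records).
#' @param y Character/factor vector of class labels, at least 2 classes.
#' @param var_floor_frac Variance floor as a fraction of the largest pooled
#'   feature variance (default 1e-9).
#'
#' @return An object of class `gnb_model`: list with `classes`, `log_prior`,
#'   `mean` and `var` (class-by-feature matrices) and `var_floor`.
#' @export
gnb_fit <- function(x, y, var_floor_frac = 1e-9) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("degenerate model: training data contain a single class", call. = FALSE)
  }
  p <- ncol(x)
  mu <- matrix(0, length(classes), p, dimnames = list(classes, colnames(x)))
  v <- mu
  for (i in seq_along(classes)) {
    xc <- x[y == classes[i], , drop = FALSE]
    mu[i, ] <- colMeans(xc)
    # ML variance (divisor n), zero for singleton classes before flooring
    v[i, ] <- colMeans(xc^2) - mu[i, ]^2
  }
  pooled_var <- colMeans(x^2) - colMeans(x)^2
  top <- max(pooled_var)
  floor_val <- if (is.finite(top) && top > 0) var_floor_frac * top else var_floor_frac
  v <- pmax(v, floor_val)
  structure(
    list(classes = classes,
         log_prior = log(as.numeric(table(factor(y, classes)) / length(y))),
         mean = mu, var = v, var_floor = floor_val),
    class = "gnb_model"
  )
}

#' Predict with a Gaussian naive Bayes model
#'
#' Argmax over classes of log-prior plus the sum of per-feature Gaussian
#' log-densities; ties go to the first class in sorted order, making
#' prediction deterministic.
#'
#' @param model A [gnb_fit()] model.
#' @param x Numeric feature matrix with the same columns as at fit time.
#' @return Character vector of predicted class labels.
#' @export
gnb_predict <- function(model, x) {
  stopifnot(inherits(model, "gnb_model"))
  x <- as.matrix(x)
  scores <- vapply(seq_along(model$classes), function(i) {
    mu <- model$mean[i, ]
    v <- model$var[i, ]
    const <- -0.5 * sum(log(2 * pi * v))
    model$log_prior[i] + const -
      0.5 * colSums((t(x) - mu)^2 / v)
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  model$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.gnb_model <- function(x, ...) {
  cat("Gaussian naive Bayes: ", length(x$classes), " classes, ",
      ncol(x$mean), " features, variance floor ",
      format(x$var_floor, digits = 3), "\n", sep = "")
  invisible(x)
}
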