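## Bernoulli Naive Bayes, implemented from scratch.
##
## theta_hat_{j,y} = (count(x_j = 1, y) + alpha) / (N_y + 2 alpha), priors are
## empirical class frequencies, and all scoring runs in log space: with
## hundreds of binary features the raw likelihood products underflow.

#' Fit a Bernoulli Naive Bayes model
#'
#' @param x a labeled `design_matrix` (from [build_design_matrix()]) or a
#'   binary matrix.
#' @param y binary outcome vector (ignored when `x` carries a label).
#' @param alpha smoothing constant (> 0); `alpha = 1` is Laplace smoothing,
#'   the customary default for Bernoulli text models.
#' @return object of class `nb_model` with `alpha`, `log_prior`, `log_theta`
#'   and `log_one_minus_theta` (features x 2 matrices with columns `"0"`,
#'   `"1"`), `feature_names`, `class_counts` and per-feature positive counts
#'   `feature_counts`.
#' @examples
#' X <- matrix(rbinom(60, 1, 0.4), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- rbinom(20, 1, 0.5)
#' if (length(unique(y)) == 2) fit <- nb_fit(X, y)
#' @export
nb_fit <- function(x, y = NULL, alpha = 1) {
  if (inherits(x, "design_matrix")) {
    if (is.null(y)) y <- x$label
    x <- x$X
  }
  if (is.null(y)) .stopf("labels are required to fit the model")
  if (!.scalar(alpha, function(a) a > 0)) .stopf("alpha must be a positive number")
  y <- as.integer(y)
  if (length(y) != nrow(x)) .stopf("label length does not match the matrix")
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  if (n0 == 0L || n1 == 0L) .stopf("both classes must be present to fit")

  count1 <- colSums(x[y == 1L, , drop = FALSE])
  count0 <- colSums(x[y == 0L, , drop = FALSE])
  theta <- cbind("0" = (count0 + alpha) / (n0 + 2 * alpha),
                 "1" = (count1 + alpha) / (n1 + 2 * alpha))
  structure(
    list(
      alpha = alpha,
      log_prior = log(c("0" = n0, "1" = n1) / (n0 + n1)),
      log_theta = log(theta),
      log_one_minus_theta = log1p(-theta),
      feature_names = colnames(x),
      class_counts = c("0" = n0, "1" = n1),
      feature_counts = cbind("0" = count0, "1" = count1)
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf(
    "<nb_model> Bernoulli NB: %d features, alpha = %g, N0 = %d, N1 = %d\n",
    length(x$feature_names), x$alpha, x$class_counts[["0"]], x$class_counts[["1"]]
  ))
  invisible(x)
}

#' Posterior probability of being a case
#'
#' Computes P(y = 1 | x) in log space (the two class log-joints are combined
#' through the logistic of their difference, the log-sum-exp guard for two
#' terms), so the result is always strictly inside (0, 1).
#'
#' @param model an `nb_model`.
#' @param x a binary feature vector, binary matrix with matching columns, or
#'   `design_matrix`.
#' @return numeric vector of posterior case probabilities.
#' @export
nb_posterior <- function(model, x) {
  stopifnot(inherits(model, "nb_model"))
  if (inherits(x, "design_matrix")) x <- x$X
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != length(model$feature_names)) {
    .stopf("feature count mismatch: model has %d features, input has %d",
           length(model$feature_names), ncol(x))
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), model$feature_names)) {
    .stopf("feature names do not match the model schema")
  }
  lj <- vapply(c("0", "1"), function(k) {
    w <- model$log_theta[, k] - model$log_one_minus_theta[, k]
    drop(x %*% w) + sum(model$log_one_minus_theta[, k]) + model$log_prior[[k]]
  }, numeric(nrow(x)))
  if (is.null(dim(lj))) lj <- matrix(lj, nrow = 1)
  unname(stats::plogis(lj[, 2] - lj[, 1]))
}

#' Variable importance by log-probability difference
#'
#' For each feature, the smoothed class-conditional log probability of the
#' negative class is subtracted from that of the positive class:
#' `log theta_hat_{j,1} - log theta_hat_{j,0}`. Smoothing keeps the statistic
#' finite even for features never seen in the negative class. The contingency
#' counts a (feature+/target+), b (feature+/target-), c (feature-/target+),
#' d (feature-/target-) are reported alongside.
#'
#' @param model a fitted `nb_model`.
#' @return data frame of class `nb_importance`, rows sorted by decreasing
#'   `log_prob_difference`.
#' @export
nb_importance <- function(model) {
  stopifnot(inherits(model, "nb_model"))
  a <- model$feature_counts[, "1"]
  b <- model$feature_counts[, "0"]
  out <- data.frame(
    feature = model$feature_names,
    log_prob_difference = model$log_theta[, "1"] - model$log_theta[, "0"],
    a = as.integer(a), b = as.integer(b),
    c = as.integer(model$class_counts[["1"]] - a),
    d = as.integer(model$class_counts[["0"]] - b),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$log_prob_difference, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nb_importance", "data.frame")
  out
}

#' Serialize / restore a model as JSON
#'
#' Round-trips exactly: probabilities are written at full precision.
#'
#' @param path file path.
#' @return `read_nb_model` returns an `nb_model`.
#' @export
read_nb_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- matrix(raw$theta, ncol = 2, dimnames = list(raw$feature_names, c("0", "1")))
  counts <- matrix(as.numeric(raw$feature_counts), ncol = 2,
                   dimnames = list(raw$feature_names, c("0", "1")))
  structure(
    list(
      alpha = raw$alpha,
      log_prior = stats::setNames(log(raw$prior), c("0", "1")),
      log_theta = log(theta),
      log_one_minus_theta = log1p(-theta),
      feature_names = raw$feature_names,
      class_counts = stats::setNames(as.integer(raw$class_counts), c("0", "1")),
      feature_counts = counts
    ),
    class = "nb_model"
  )
}

#' @rdname read_nb_model
#' @param model an `nb_model`.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  jsonlite::write_json(
    list(
      alpha = model$alpha,
      prior = unname(exp(model$log_prior)),
      theta = unname(as.vector(exp(model$log_theta))),
      feature_names = model$feature_names,
      class_counts = unname(model$class_counts),
      feature_counts = unname(as.vector(model$feature_counts))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
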