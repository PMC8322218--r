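## Sensitivity-targeted threshold selection, the repeated 80/20 split
## calibration protocol, ROC/AUC, and cross-scenario evaluation.

#' Calibration protocol configuration
#'
#' Defaults reproduce the reference protocol: 90% target sensitivity, one
#' hundred iterations of an 80/20 random train/validation split.
#'
#' @param target_sensitivity fraction of true cases the threshold must
#'   capture, in (0, 1].
#' @param n_iterations number of repeated splits.
#' @param train_fraction training share of each split, in (0, 1).
#' @param seed integer seed; every split is derived from it.
#' @param alpha Naive Bayes smoothing constant passthrough.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(target_sensitivity = 0.90, n_iterations = 100L,
                               train_fraction = 0.80, seed = 1L, alpha = 1) {
  if (!.scalar(target_sensitivity, function(x) x > 0 && x <= 1)) {
    .stopf("target_sensitivity must lie in (0, 1]")
  }
  if (!.scalar(train_fraction, function(x) x > 0 && x < 1)) {
    .stopf("train_fraction must lie in (0, 1)")
  }
  if (!.scalar(n_iterations, function(x) x >= 1)) .stopf("n_iterations must be >= 1")
  structure(
    list(
      target_sensitivity = target_sensitivity,
      n_iterations = as.integer(n_iterations),
      train_fraction = train_fraction,
      seed = as.integer(seed), alpha = alpha
    ),
    class = "calibration_config"
  )
}

#' Select the posterior threshold capturing a target share of cases
#'
#' The threshold is the smallest score value that still captures at least
#' `ceiling(target * P)` of the `P` positives, i.e. the
#' `ceiling(target * P)`-th largest positive score; records are tagged on
#' `score >= threshold` (ties inclusive). Raising the threshold to the next
#' distinct score value would break the sensitivity guarantee.
#'
#' @param scores posterior probabilities.
#' @param labels 0/1 outcome vector aligned to `scores`.
#' @param target target sensitivity in (0, 1].
#' @return list with `threshold`, `tagged_fraction` (share of all records
#'   tagged), `precision` (positives among tagged / tagged) and `sensitivity`
#'   (share of positives captured, always >= `target`).
#' @examples
#' # perfectly separated scores: threshold lands on the positives
#' s <- c(rep(0.9, 5), rep(0.1, 20))
#' y <- c(rep(1, 5), rep(0, 20))
#' select_threshold(s, y, 0.9)$precision
#' @export
select_threshold <- function(scores, labels, target = 0.90) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) .stopf("scores and labels are misaligned")
  pos <- scores[labels == 1L]
  if (!length(pos)) .stopf("threshold selection requires at least one positive")
  k <- ceiling(target * length(pos))
  thr <- sort(pos, decreasing = TRUE)[k]
  tagged <- scores >= thr
  list(
    threshold = thr,
    tagged_fraction = mean(tagged),
    precision = sum(labels[tagged] == 1L) / sum(tagged),
    sensitivity = mean(pos >= thr)
  )
}

#' ROC curve and AUC
#'
#' Standard threshold sweep over all distinct score values (tied scores
#' collapse into a single step), with AUC by the trapezoidal rule - exactly
#' the Mann-Whitney pairwise statistic with tie correction.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcome vector; both classes must be present.
#' @return object of class `roc_curve`: list with `points` (data frame `fpr`,
#'   `tpr`, sorted by `fpr`, containing (0,0) and (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) .stopf("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE) # end of each tie group
  tpr <- c(0, cumsum(y == 1L)[last] / n1)
  fpr <- c(0, cumsum(y == 0L)[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

## one calibration iteration on a given split
.calibrate_once <- function(X, y, train_idx, target, alpha) {
  fit <- nb_fit(X[train_idx, , drop = FALSE], y[train_idx], alpha = alpha)
  val <- setdiff(seq_along(y), train_idx)
  scores <- nb_posterior(fit, X[val, , drop = FALSE])
  sel <- select_threshold(scores, y[val], target)
  sel$auc <- roc_curve(scores, y[val])$auc
  sel
}

#' Calibrate the tagging threshold over repeated splits
#'
#' Each iteration draws a random train/validation split, fits the Bernoulli
#' NB model on the training share, scores the validation share, and selects
#' the threshold achieving the target sensitivity on the validation scores.
#' Degenerate splits (missing a class in training, or no validation
#' positives) are redrawn, so exactly `n_iterations` usable iterations are
#' recorded. Aggregates are means and (n-1)-denominator standard deviations.
#'
#' @param dm a labeled `design_matrix` with at least two positives.
#' @param config a [calibration_config()].
#' @return object of class `calibration_result`: `per_iteration` data frame
#'   (threshold, tagged_fraction, precision, sensitivity, auc) plus
#'   `*_mean` / `*_sd` aggregates and the config.
#' @export
calibrate <- function(dm, config = calibration_config()) {
  stopifnot(inherits(dm, "design_matrix"), inherits(config, "calibration_config"))
  y <- dm$label
  if (is.null(y)) .stopf("calibration requires a labeled design matrix")
  if (sum(y == 1L) < 2L) .stopf("calibration requires at least two positives")
  X <- dm$X
  n <- length(y)
  n_train <- max(1L, floor(config$train_fraction * n))

  rows <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    res <- NULL
    for (attempt in 1:50) {
      set.seed(derive_seed(config$seed, it * 1000L + attempt))
      train_idx <- sample.int(n, n_train)
      yt <- y[train_idx]
      yv <- y[-train_idx]
      if (length(unique(yt)) < 2L || !any(yv == 1L)) next # degenerate, redraw
      res <- .calibrate_once(X, y, train_idx, config$target_sensitivity, config$alpha)
      break
    }
    if (is.null(res)) .stopf("no usable split found in 50 attempts at iteration %d", it)
    rows[[it]] <- as.data.frame(res)
  }
  per <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(per[[v]]), sd = stats::sd(per[[v]]))
  structure(
    list(
      per_iteration = per,
      threshold_mean = agg("threshold")[["mean"]],
      threshold_sd = agg("threshold")[["sd"]],
      tagged_fraction_mean = agg("tagged_fraction")[["mean"]],
      tagged_fraction_sd = agg("tagged_fraction")[["sd"]],
      precision_mean = agg("precision")[["mean"]],
      precision_sd = agg("precision")[["sd"]],
      auc_mean = agg("auc")[["mean"]],
      auc_sd = agg("auc")[["sd"]],
      config = config
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<calibration_result> %d iterations (target sensitivity %.2f)\n",
      "  threshold:       %.4f (SD %.4f)\n",
      "  tagged fraction: %.3f (SD %.3f)\n",
      "  precision:       %.3f (SD %.3f)\n",
      "  AUC:             %.3f (SD %.3f)\n"
    ),
    nrow(x$per_iteration), x$config$target_sensitivity,
    x$threshold_mean, x$threshold_sd,
    x$tagged_fraction_mean, x$tagged_fraction_sd,
    x$precision_mean, x$precision_sd, x$auc_mean, x$auc_sd
  ))
  invisible(x)
}

#' Serialize a calibration result as JSON
#' @param result a `calibration_result`.
#' @param path file path.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  out <- result
  out$config <- unclass(out$config)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Cross-scenario (year/state) evaluation
#'
#' Fits on one corpus's design matrix and evaluates on another sharing the
#' same frozen feature schema: reports the AUC on the test corpus and the
#' false positive rate incurred at the threshold achieving the target true
#' positive rate on the test scores (the "necessary false positive rate").
#'
#' @param train_dm,test_dm labeled `design_matrix` objects with identical
#'   feature columns.
#' @param target required true positive rate (default 0.9).
#' @param alpha smoothing constant.
#' @return list with `auc` and `required_fpr`.
#' @export
cross_scenario_eval <- function(train_dm, test_dm, target = 0.90, alpha = 1) {
  stopifnot(inherits(train_dm, "design_matrix"), inherits(test_dm, "design_matrix"))
  if (!identical(colnames(train_dm$X), colnames(test_dm$X))) {
    .stopf("train and test design matrices use different feature schemas")
  }
  if (is.null(train_dm$label) || is.null(test_dm$label)) {
    .stopf("cross-scenario evaluation requires labeled matrices")
  }
  fit <- nb_fit(train_dm, alpha = alpha)
  scores <- nb_posterior(fit, test_dm)
  y <- test_dm$label
  sel <- select_threshold(scores, y, target)
  list(
    auc = roc_curve(scores, y)$auc,
    required_fpr = mean(scores[y == 0L] >= sel$threshold)
  )
}
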