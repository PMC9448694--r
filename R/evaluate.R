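# Statistical evaluation of a predicted depth index against a reference:
# correlation, simple regression, Q-Q agreement, confusion matrix, RMSE.

#' Pearson correlation coefficient
#'
#' @param a,b Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ")
  if (length(a) < 2L) stop("need at least 2 observations")
  if (sd_pop(a) == 0 || sd_pop(b) == 0) stop("zero variance")
  stats::cor(a, b)
}

#' Least-squares line of one series on another
#'
#' Fits `b ~ a` by ordinary least squares. For the simple linear fit the
#' coefficient of determination equals the squared Pearson correlation.
#'
#' @param a Predictor series.
#' @param b Response series.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @examples
#' regression_fit(1:10, 2 * (1:10) + 1)
#' @export
regression_fit <- function(a, b) {
  r <- pearson_r(a, b)
  slope <- r * sd_pop(b) / sd_pop(a)
  list(slope = slope, intercept = mean(b) - slope * mean(a),
       r_squared = r^2)
}

#' Matched empirical quantiles of two samples
#'
#' Quantiles at probabilities `(i - 0.5) / n`; samples from the same
#' distribution fall on the 45-degree line.
#'
#' @param a,b Numeric samples (any lengths, nonempty).
#' @param n_quantiles Number of probability points (default 100).
#' @return data.frame with columns `prob`, `qa`, `qb`.
#' @export
qq_pairs <- function(a, b, n_quantiles = 100) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input")
  p <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  data.frame(prob = p,
             qa = as.numeric(stats::quantile(a, p, names = FALSE)),
             qb = as.numeric(stats::quantile(b, p, names = FALSE)))
}

#' Root mean square error
#'
#' @param a,b Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ")
  if (length(a) < 1L) stop("empty input")
  sqrt(mean((a - b)^2))
}

#' Multiclass confusion matrix with per-class sensitivity/specificity
#'
#' Counts a square confusion matrix over the anesthetic states and
#' derives per-class sensitivity `TP/(TP+FN)`, one-vs-rest specificity
#' `TN/(TN+FP)` and overall accuracy.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param levels Label set and order (default [state_levels()]).
#' @return List with `confusion` (truth in rows), `accuracy`,
#'   `sensitivity`, `specificity` (named by class), `n`.
#' @export
classification_report <- function(truth, predicted, levels = state_levels()) {
  if (length(truth) != length(predicted)) stop("lengths differ")
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad))
    stop(sprintf("labels outside the level set: %s", paste(bad, collapse = ", ")))
  tf <- factor(truth, levels = levels)
  pf <- factor(predicted, levels = levels)
  cm <- table(truth = tf, predicted = pf)
  n <- sum(cm)
  sens <- spec <- stats::setNames(numeric(length(levels)), levels)
  for (cl in levels) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens[cl] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[cl] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  list(confusion = cm, accuracy = sum(diag(cm)) / n,
       sensitivity = sens, specificity = spec, n = n)
}

#' Full evaluation report of a predicted index against a reference
#'
#' Bundles every metric of the evaluation battery: Pearson r, regression
#' fit and R-squared, RMSE, Q-Q pairs, and (from the state labels implied
#' by the two index series) the confusion matrix with accuracy,
#' sensitivity and specificity. Pairs where either series is `NA`
#' (blanked reference) are dropped from the paired metrics.
#'
#' @param predicted Predicted index series in `[0, 100]`.
#' @param reference Reference index series (same length; may contain
#'   `NA`).
#' @param n_quantiles Q-Q resolution.
#' @return Object of class `doa_report`.
#' @export
evaluate_index <- function(predicted, reference, n_quantiles = 100) {
  if (length(predicted) != length(reference)) stop("lengths differ")
  ok <- !is.na(predicted) & !is.na(reference)
  if (sum(ok) < 2L) stop("fewer than 2 valid pairs")
  p <- predicted[ok]; r <- reference[ok]
  reg <- regression_fit(r, p)
  cls <- classification_report(classify_state(r), classify_state(p))
  structure(list(
    pearson_r = pearson_r(p, r),
    r_squared = reg$r_squared,
    slope = reg$slope, intercept = reg$intercept,
    rmse = rmse(p, r),
    qq = qq_pairs(r, p, n_quantiles),
    confusion = cls$confusion, accuracy = cls$accuracy,
    sensitivity = cls$sensitivity, specificity = cls$specificity,
    n = sum(ok), n_dropped = sum(!ok)), class = "doa_report")
}

#' @export
print.doa_report <- function(x, ...) {
  cat("DoA evaluation report\n")
  cat(sprintf("  n = %d paired values (%d dropped as blank)\n", x$n, x$n_dropped))
  cat(sprintf("  Pearson r = %.3f, R^2 = %.3f, RMSE = %.2f\n",
              x$pearson_r, x$r_squared, x$rmse))
  cat(sprintf("  state accuracy = %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A [evaluate_index()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "doa_report"))
  obj <- unclass(report)
  obj$confusion <- as.data.frame(report$confusion)
  obj$config_hash <- attr(report, "config_hash")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
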