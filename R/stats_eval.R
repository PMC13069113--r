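#' Upper confidence bound on the accuracy of a random k-class classifier
#'
#' Adjusted-Wald (Agresti-Coull) upper limit for the accuracy a random
#' classifier can reach by chance over a finite balanced session: with
#' n = `n_per_class * n_classes` trials, success probability
#' 1/`n_classes`, and z the upper 1 - alpha/2 normal quantile, the
#' adjusted counts are n~ = n + z^2 and
#' p~ = (n / n_classes + z^2 / 2) / n~, and the bound is
#' 100 (p~ + z sqrt(p~ (1 - p~) / n~)) percent. Observed accuracies above
#' this bound are unlikely (at level alpha) to come from guessing.
#'
#' @param n_per_class Trials per class.
#' @param n_classes Number of classes (>= 2).
#' @param alpha Significance level in (0, 1); 0.01 gives the 99% bound.
#' @return An object of class `chance_bound` with fields `n_per_class`,
#'   `n_classes`, `alpha` and `bound` (percent).
#' @export
chance_upper_bound <- function(n_per_class, n_classes, alpha) {
  if (n_per_class < 1 || n_classes < 2) stop("need n_per_class >= 1, n_classes >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  n <- n_per_class * n_classes
  n_adj <- n + z^2
  p_adj <- (n / n_classes + z^2 / 2) / n_adj
  bound <- 100 * (p_adj + z * sqrt(p_adj * (1 - p_adj) / n_adj))
  structure(list(n_per_class = n_per_class, n_classes = n_classes,
                 alpha = alpha, bound = bound),
            class = "chance_bound")
}

#' @export
print.chance_bound <- function(x, ...) {
  cat(sprintf("<chance_bound> %d-class, %d trials/class: %.1f%% at the %g%% level\n",
              x$n_classes, x$n_per_class, x$bound, 100 * (1 - x$alpha)))
  invisible(x)
}

#' Mean and population standard deviation of accuracies
#'
#' Subject-level accuracy summaries use the population (divisor-n)
#' standard deviation.
#'
#' @param values Numeric vector of accuracies in percent.
#' @return List with `mean` and `sd` (percent).
#' @export
summarize_accuracies <- function(values) {
  if (!length(values)) stop("empty accuracy list")
  m <- mean(values)
  list(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Welch's two-sample t-test from group summaries
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed from each group's mean, standard deviation and
#' size: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) and
#' df = (v1 + v2)^2 / (v1^2/(n1-1) + v2^2/(n2-1)) with vi = si^2/ni.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's summary.
#' @return An object of class `welch_result` with `t`, `df`, `p` (two
#'   sided) and both group summaries.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
    stop("standard deviations must be >= 0 and not both zero")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 group1 = list(mean = mean1, sd = sd1, n = n1),
                 group2 = list(mean = mean2, sd = sd2, n = n2)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.3f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  cat(sprintf("  group 1: mean %.2f, sd %.2f, n %d | group 2: mean %.2f, sd %.2f, n %d\n",
              x$group1$mean, x$group1$sd, x$group1$n,
              x$group2$mean, x$group2$sd, x$group2$n))
  invisible(x)
}

#' Accuracy difference between primary and secondary frequency couples
#'
#' @param primary_mean,secondary_mean Mean accuracies in percent.
#' @return `primary_mean - secondary_mean`, percent.
#' @export
accuracy_change <- function(primary_mean, secondary_mean) {
  stopifnot(primary_mean >= 0, primary_mean <= 100,
            secondary_mean >= 0, secondary_mean <= 100)
  primary_mean - secondary_mean
}

#' Count accuracies strictly above a threshold
#'
#' @param values Numeric vector of accuracies in percent.
#' @param threshold Threshold in percent.
#' @return Integer count of values strictly greater than `threshold`.
#' @export
count_above <- function(values, threshold) {
  stopifnot(threshold >= 0, threshold <= 100)
  sum(values > threshold)
}

#' Bundled per-subject reference accuracy tables
#'
#' Transcribed summary tables from a published 20-subject visual-imagery
#' BCI study, shipped as plain-text fixtures. `subject_accuracies()`
#' returns, per subject, the selected frequency couple, the offline
#' cross-validation mean and standard deviation, and the online session
#' accuracy (all percent). `frequency_comparison()` returns, for the
#' eight subjects who repeated the offline session with the unselected
#' (secondary) couple, both sessions' means and standard deviations.
#'
#' @return A data frame.
#' @export
subject_accuracies <- function() {
  utils::read.csv(system.file("extdata", "subject_accuracies.csv",
                              package = "vibci"))
}

#' @rdname subject_accuracies
#' @export
frequency_comparison <- function() {
  utils::read.csv(system.file("extdata", "frequency_comparison.csv",
                              package = "vibci"))
}
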