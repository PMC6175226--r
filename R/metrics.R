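#' Replication-averaged performance metrics
#'
#' The four performance measures aggregate replicated estimates of one
#' target coefficient against its generating truth `z`:
#' mean bias \eqn{\frac{1}{m}\sum (z - \hat z_i)} (signed, truth minus
#' estimate), mean error \eqn{\frac{1}{m}\sum |z - \hat z_i|}, coverage
#' (fraction of 95% CIs containing `z`, closed intervals) and power
#' (fraction of two-sided Wald tests rejecting the stated null).  All are
#' computed over converged replications only; an empty input yields `NA`
#' (the undefined-metric marker).
#'
#' @param estimates Numeric vector of converged point estimates.
#' @param truth The generating value of the target coefficient.
#' @return `mean_bias`/`mean_error`: a single number; see below for the
#'   interval- and test-based metrics.
#' @name performance-metrics
NULL

#' @rdname performance-metrics
#' @export
mean_bias <- function(estimates, truth) {
  if (length(estimates) == 0) return(NA_real_)
  mean(truth - estimates)
}

#' @rdname performance-metrics
#' @export
mean_error <- function(estimates, truth) {
  if (length(estimates) == 0) return(NA_real_)
  mean(abs(truth - estimates))
}

#' @rdname performance-metrics
#' @param ci_low,ci_high Numeric vectors of 95% interval bounds.
#' @export
coverage <- function(ci_low, ci_high, truth) {
  stopifnot(length(ci_low) == length(ci_high))
  if (length(ci_low) == 0) return(NA_real_)
  mean(ci_low <= truth & truth <= ci_high)
}

#' @rdname performance-metrics
#' @param se Numeric vector of standard errors matching `estimates`.
#' @param null_value The null hypothesis value: 0 for main-effect
#'   settings, 0.2 for interaction settings.
#' @export
power <- function(estimates, se, null_value = 0) {
  stopifnot(length(estimates) == length(se))
  if (length(estimates) == 0) return(NA_real_)
  mean(abs(estimates - null_value) / se > stats::qnorm(0.975))
}

#' Summarize replicated fit results into a metrics row
#'
#' Collapses a table of per-replication fit records for one model into the
#' five-metric summary.  Bias, error, coverage and power use converged
#' replications only; the convergence rate (converged / total) is reported
#' alongside, plus the combined display metric `(coverage + power)/2`.
#'
#' @param fits Data frame with columns `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `converged` (one row per replication).
#' @param truth Generating value of the target coefficient.
#' @param null_value Null value for the power calculation.
#' @return One-row data frame: `n_iterations_total`, `n_converged`,
#'   `mean_bias`, `mean_error`, `coverage`, `power`, `convergence_rate`,
#'   `coverage_power_mean`.
#' @export
summarize_fits <- function(fits, truth, null_value = 0) {
  conv <- fits[!is.na(fits$converged) & fits$converged, , drop = FALSE]
  cov <- coverage(conv$ci_lo, conv$ci_hi, truth)
  pow <- power(conv$estimate, conv$se, null_value)
  data.frame(
    n_iterations_total = nrow(fits),
    n_converged = nrow(conv),
    mean_bias = mean_bias(conv$estimate, truth),
    mean_error = mean_error(conv$estimate, truth),
    coverage = cov,
    power = pow,
    convergence_rate = if (nrow(fits) == 0) NA_real_
                       else nrow(conv) / nrow(fits),
    coverage_power_mean = (cov + pow) / 2)
}
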