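#' First stage: per-study least-squares estimates
#'
#' Fits, separately in every study, the ordinary least-squares regression
#' of the outcome on an intercept, the exposure and the covariate (plus the
#' exposure-by-covariate product when the target is the interaction), and
#' extracts the target coefficient with its squared standard error.
#' Studies whose design is singular for the target — a constant covariate
#' or constant exposure within the study — are marked `estimable = FALSE`
#' and excluded from pooling; they count against two-stage convergence.
#'
#' Exact-fit degenerate inputs would give a zero sampling variance, so
#' variances are floored at `1e-12` to keep inverse-variance weights
#' finite.
#'
#' @param dataset An `ipd_dataset` (or any data frame with columns
#'   `study_id`, `y`, `group`, `x`).
#' @param target `"exposure"` or `"interaction"`.
#' @return A data frame of class `study_estimates` with columns
#'   `study_id`, `coef`, `var`, `n`, `estimable`.
#' @export
first_stage <- function(dataset, target = c("exposure", "interaction")) {
  target <- match.arg(target)
  ids <- sort(unique(dataset$study_id))
  form <- if (target == "exposure") y ~ group + x else y ~ group * x
  coef_name <- if (target == "exposure") "group" else "group:x"
  out <- lapply(ids, function(j) {
    d <- dataset[dataset$study_id == j, , drop = FALSE]
    row <- data.frame(study_id = j, coef = NA_real_, var = NA_real_,
                      n = nrow(d), estimable = FALSE)
    if (nrow(d) < 4) return(row)
    fit <- tryCatch(stats::lm(form, data = d), error = function(e) NULL)
    if (is.null(fit)) return(row)
    sm <- summary(fit)$coefficients
    if (!coef_name %in% rownames(sm)) return(row)
    est <- sm[coef_name, "Estimate"]
    se <- sm[coef_name, "Std. Error"]
    if (!is.finite(est) || !is.finite(se)) return(row)
    row$coef <- est
    row$var <- max(se^2, 1e-12)
    row$estimable <- TRUE
    row
  })
  structure(do.call(rbind, out), class = c("study_estimates", "data.frame"))
}

# Shared validation for the pooling routines.
pool_input <- function(estimates) {
  est <- estimates[estimates$estimable, , drop = FALSE]
  if (nrow(est) < 2)
    stop("pooling needs at least 2 estimable studies", call. = FALSE)
  if (any(est$var <= 0))
    stop("estimable studies must have positive sampling variance",
         call. = FALSE)
  est
}

pooled_estimate <- function(theta, se, tau2, Q, k, method,
                            notes = character()) {
  z <- stats::qnorm(0.975)
  structure(list(theta_hat = theta, se = se,
                 ci_low = theta - z * se, ci_high = theta + z * se,
                 tau2 = tau2, Q = Q, k_used = k, method = method,
                 notes = notes),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s pooled estimate: %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$method, x$theta_hat, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  tau2 = %.5f, Q = %.4f, k = %d\n", x$tau2, x$Q, x$k_used))
  invisible(x)
}

# Cochran's Q and the fixed-effect mean under inverse-variance weights.
q_statistic <- function(yi, vi) {
  w <- 1 / vi
  mu <- sum(w * yi) / sum(w)
  list(Q = sum(w * (yi - mu)^2), mu = mu, w = w)
}

#' Random-effects pooling with the DerSimonian-Laird estimator
#'
#' Classic moment-based random-effects meta-analysis.  With
#' inverse-variance weights \eqn{\hat w_j = 1/\hat\sigma_j^2} and the
#' fixed-effect mean, the heterogeneity statistic is
#' \eqn{Q = \sum \hat w_j (\hat\gamma_j - \bar\gamma)^2} and
#' \deqn{\hat\tau^2_{DL} = \max\left(0,\;
#'   \frac{Q - (k - 1)}{\sum \hat w_j - \sum \hat w_j^2 / \sum \hat w_j}
#'   \right).}
#' Studies are then re-weighted by \eqn{1/(\hat\sigma_j^2 + \hat\tau^2)}
#' to give the pooled estimate, its standard error
#' \eqn{(\sum w^*_j)^{-1/2}} and a normal Wald 95% CI.
#'
#' @param estimates A `study_estimates` table (from [first_stage()] or
#'   [read_study_estimates()]); only `estimable` rows are pooled, and at
#'   least 2 are required.
#' @return A `pooled_estimate` (method `"DL"`).
#' @export
pool_DL <- function(estimates) {
  est <- pool_input(estimates)
  qs <- q_statistic(est$coef, est$var)
  k <- nrow(est)
  w <- qs$w
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (qs$Q - (k - 1)) / denom)
  ws <- 1 / (est$var + tau2)
  theta <- sum(ws * est$coef) / sum(ws)
  pooled_estimate(theta, 1 / sqrt(sum(ws)), tau2, qs$Q, k, "DL")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' @inheritParams pool_DL
#' @return A `pooled_estimate` (method `"FE"`, `tau2 = 0`).
#' @export
pool_FE <- function(estimates) {
  est <- pool_input(estimates)
  qs <- q_statistic(est$coef, est$var)
  pooled_estimate(qs$mu, 1 / sqrt(sum(qs$w)), 0, qs$Q, nrow(est), "FE")
}

# Restricted log-likelihood of the standard random-effects model at a
# given tau2 (constant terms dropped).
reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  theta <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - theta)^2))
}

#' Random-effects pooling with REML heterogeneity estimation
#'
#' Estimates the between-study variance by maximizing the restricted
#' log-likelihood of the standard random-effects model over
#' \eqn{\tau^2 \ge 0} (bounded one-dimensional optimization, tolerance
#' `1e-10`, with an explicit boundary check at zero), then pools exactly as
#' [pool_DL()] but with the REML \eqn{\hat\tau^2}.  This is the default
#' second-stage method of the harness ("two-stage model d").  If the
#' optimization fails the DerSimonian-Laird value is used and a note is
#' recorded.
#'
#' @inheritParams pool_DL
#' @return A `pooled_estimate` (method `"REML"`).
#' @export
pool_REML <- function(estimates) {
  est <- pool_input(estimates)
  yi <- est$coef; vi <- est$var
  k <- nrow(est)
  qs <- q_statistic(yi, vi)
  upper <- max(1e-6, 10 * stats::var(yi), 10 * max(vi))
  notes <- character()
  opt <- tryCatch(
    stats::optimize(reml_loglik, c(0, upper), yi = yi, vi = vi,
                    maximum = TRUE, tol = 1e-10),
    error = function(e) NULL)
  if (is.null(opt)) {
    notes <- "REML optimization failed; DerSimonian-Laird value used"
    tau2 <- pool_DL(estimates)$tau2
  } else {
    tau2 <- if (reml_loglik(0, yi, vi) >= opt$objective) 0 else opt$maximum
  }
  ws <- 1 / (vi + tau2)
  theta <- sum(ws * yi) / sum(ws)
  pooled_estimate(theta, 1 / sqrt(sum(ws)), tau2, qs$Q, k, "REML", notes)
}

#' Two-stage IPD meta-analysis
#'
#' Runs the full two-stage pipeline: per-study regressions
#' ([first_stage()]) followed by random-effects pooling of the target
#' coefficient.  Non-convergence for the two-stage model means fewer than
#' 2 estimable studies (e.g. all-constant covariates under varying
#' prevalence) — the pooling itself is closed-form or a bounded 1-D
#' search and does not otherwise fail.
#'
#' @param dataset An `ipd_dataset`.
#' @param target `"exposure"` or `"interaction"`.
#' @param method Second-stage heterogeneity estimator: `"REML"` (default),
#'   `"DL"` or `"FE"`.
#' @return A `fit_result` with `model_id = "d"`; `n_studies_used` counts
#'   the estimable studies.  The pooled-object details (tau2, Q, the
#'   DL companion estimate) are attached as attribute `pooled`.
#' @export
fit_twostage <- function(dataset, target = c("exposure", "interaction"),
                         method = c("REML", "DL", "FE")) {
  target <- match.arg(target)
  method <- match.arg(method)
  est <- first_stage(dataset, target)
  k_total <- nrow(est)
  k_est <- sum(est$estimable)
  if (k_est < 2) {
    fr <- fit_result("d", target, NA_real_, NA_real_, converged = FALSE,
                     n_studies_used = k_est,
                     notes = "fewer than 2 estimable studies")
    attr(fr, "first_stage") <- est
    return(fr)
  }
  pooled <- switch(method, REML = pool_REML(est), DL = pool_DL(est),
                   FE = pool_FE(est))
  fr <- fit_result("d", target, pooled$theta_hat, pooled$se,
                   converged = TRUE,
                   tau2_estimates = c(pooled = pooled$tau2),
                   n_studies_used = k_est,
                   notes = if (k_est < k_total)
                     sprintf("%d of %d studies inestimable, excluded",
                             k_total - k_est, k_total) else character())
  attr(fr, "pooled") <- pooled
  attr(fr, "first_stage") <- est
  fr
}
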