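#' Convert a target I-squared to a between-study variance
#'
#' Heterogeneity in the generator is parameterized through I², the ratio of
#' between-study to total variance, \eqn{I^2 = \tau^2 / (\tau^2 + \sigma^2)}.
#' Inverting gives the between-study variance \eqn{\tau^2} that, against a
#' residual variance \eqn{\sigma^2}, produces the requested I².
#'
#' @param i2 Target I² in `[0, 1)`.
#' @param sigma2 Residual (within-study) variance, strictly positive.
#' @return The between-study variance \eqn{\tau^2 = I^2 \sigma^2 / (1 - I^2)}.
#' @examples
#' i2_to_tau2(0.5, 1)  # 1
#' i2_to_tau2(0, 1)    # 0
#' @export
i2_to_tau2 <- function(i2, sigma2) {
  if (!is.numeric(i2) || any(i2 < 0) || any(i2 >= 1))
    stop("`i2` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(sigma2) || any(sigma2 <= 0))
    stop("`sigma2` must be strictly positive", call. = FALSE)
  i2 * sigma2 / (1 - i2)
}

#' Draw per-study sample sizes
#'
#' Study sizes are i.i.d. integers, uniform on
#' `[round(range[1] * mean_size), round(range[2] * mean_size)]`, so the
#' expected size equals `mean_size` for a symmetric range.  Draws use the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param k Number of studies (at least 2 — a meta-analysis of one study is
#'   refused).
#' @param mean_size Mean number of patients per study (at least 10).
#' @param range Length-2 multiplier pair `(lo, hi)` applied to `mean_size`.
#' @return Integer vector of `k` study sizes.
#' @export
draw_study_sizes <- function(k, mean_size, range = c(0.5, 1.5)) {
  if (!is.numeric(k) || length(k) != 1 || k < 2)
    stop("meta-analysis needs at least 2 studies (`k` >= 2)", call. = FALSE)
  if (!is.numeric(mean_size) || length(mean_size) != 1 || mean_size < 10)
    stop("`mean_size` must be at least 10", call. = FALSE)
  if (length(range) != 2 || range[1] <= 0 || range[2] < range[1])
    stop("`range` must be an increasing positive pair", call. = FALSE)
  lo <- round(range[1] * mean_size)
  hi <- round(range[2] * mean_size)
  lo <- max(lo, 2L)
  sample(seq.int(lo, hi), size = k, replace = TRUE)
}

#' Specify a generative IPD meta-analysis scenario
#'
#' A `scenario_spec` holds the full generative configuration for one
#' simulated IPD meta-analysis: the number of studies `k` and mean study
#' size, the fixed mean coefficients (intercept `gamma0`, exposure `gamma1`,
#' covariate `gamma2`, interaction `gamma3`), target I² heterogeneity per
#' coefficient, the residual-SD regime, the covariate type, the
#' random-effects distribution, and the small-study selection fraction.
#' Use [setting_preset()] for the eight named simulation settings.
#'
#' @param n_studies Number of studies `k` (>= 2).
#' @param mean_study_size Mean patients per study (>= 10).
#' @param gamma0,gamma1,gamma2,gamma3 Fixed mean intercept, exposure,
#'   covariate and interaction coefficients.  `gamma3 = 0` with
#'   `i2_interaction = 0` disables the interaction in generation.
#' @param i2_intercept,i2_exposure,i2_covariate,i2_interaction Target I² in
#'   `[0, 1)` for each random-effects component, measured against the
#'   residual variance `sigma_mean^2`.
#' @param sigma_mean Mean residual SD across studies (> 0; 1 in most
#'   settings).
#' @param sigma_sd Between-study SD of the residual SD (0 = fixed residual
#'   SD; 0.5 in the varying-variance setting).  Positive values draw each
#'   study's residual SD from a normal truncated below at 0.05.
#' @param covariate_kind `"continuous"` (standard normal) or `"binary"`
#'   (Bernoulli).
#' @param covariate_prevalence_varying For a binary covariate, draw each
#'   study's prevalence uniformly on `[0, 1]` instead of fixing it at 0.5.
#' @param exposure_prob Bernoulli probability of exposure (`group = 1`);
#'   0.5 throughout the stated designs.
#' @param re_distribution `"normal"` or `"skew_normal"` random effects.
#' @param re_skewness,re_kurtosis Moment targets for the skew-normal
#'   generator (defaults: skewness 1, kurtosis 4).
#' @param kurtosis_convention Whether `re_kurtosis` is "total" kurtosis
#'   (normal = 3, the default reading) or "excess" (normal = 0).
#' @param selection_fraction Fraction of studies removed by the small-study
#'   filter ([apply_small_study_filter()]); 0 disables selection.
#' @param size_range Study-size multiplier pair passed to
#'   [draw_study_sizes()].
#' @param centre_covariate Centre the continuous covariate at the study
#'   level (off by default).
#' @param seed Optional integer replication seed; when set,
#'   [generate_ipd()] is bit-reproducible.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_studies,
                          mean_study_size,
                          gamma0 = 1, gamma1 = 0.5, gamma2 = 0.3, gamma3 = 0,
                          i2_intercept = 0, i2_exposure = 0,
                          i2_covariate = 0, i2_interaction = 0,
                          sigma_mean = 1, sigma_sd = 0,
                          covariate_kind = c("continuous", "binary"),
                          covariate_prevalence_varying = FALSE,
                          exposure_prob = 0.5,
                          re_distribution = c("normal", "skew_normal"),
                          re_skewness = 1, re_kurtosis = 4,
                          kurtosis_convention = c("total", "excess"),
                          selection_fraction = 0,
                          size_range = c(0.5, 1.5),
                          centre_covariate = FALSE,
                          seed = NULL) {
  covariate_kind <- match.arg(covariate_kind)
  re_distribution <- match.arg(re_distribution)
  kurtosis_convention <- match.arg(kurtosis_convention)
  i2 <- c(intercept = i2_intercept, exposure = i2_exposure,
          covariate = i2_covariate, interaction = i2_interaction)
  if (any(i2 < 0) || any(i2 >= 1))
    stop("all I² values must lie in [0, 1)", call. = FALSE)
  if (sigma_mean <= 0) stop("`sigma_mean` must be positive", call. = FALSE)
  if (sigma_sd < 0) stop("`sigma_sd` must be non-negative", call. = FALSE)
  if (exposure_prob <= 0 || exposure_prob >= 1)
    stop("`exposure_prob` must lie in (0, 1)", call. = FALSE)
  if (selection_fraction < 0 || selection_fraction >= 1)
    stop("`selection_fraction` must lie in [0, 1)", call. = FALSE)
  if (n_studies < 2) stop("`n_studies` must be at least 2", call. = FALSE)
  if (mean_study_size < 10)
    stop("`mean_study_size` must be at least 10", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(n_studies = as.integer(n_studies),
         mean_study_size = as.integer(mean_study_size),
         gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
         i2_intercept = i2_intercept, i2_exposure = i2_exposure,
         i2_covariate = i2_covariate, i2_interaction = i2_interaction,
         sigma_mean = sigma_mean, sigma_sd = sigma_sd,
         covariate_kind = covariate_kind,
         covariate_prevalence_varying = covariate_prevalence_varying,
         exposure_prob = exposure_prob,
         re_distribution = re_distribution,
         re_skewness = re_skewness, re_kurtosis = re_kurtosis,
         kurtosis_convention = kurtosis_convention,
         selection_fraction = selection_fraction,
         size_range = size_range,
         centre_covariate = centre_covariate,
         seed = seed),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("IPD scenario:", x$n_studies, "studies, mean size",
      x$mean_study_size, "\n")
  cat(sprintf("  gamma = (%g, %g, %g, %g)  sigma = %g (sd %g)\n",
              x$gamma0, x$gamma1, x$gamma2, x$gamma3,
              x$sigma_mean, x$sigma_sd))
  cat(sprintf("  I2 = (int %g, exp %g, cov %g, int'n %g)  covariate: %s%s\n",
              x$i2_intercept, x$i2_exposure, x$i2_covariate,
              x$i2_interaction, x$covariate_kind,
              if (x$covariate_prevalence_varying) " (varying prevalence)"
              else ""))
  cat(sprintf("  random effects: %s; selection fraction: %g\n",
              x$re_distribution, x$selection_fraction))
  invisible(x)
}

#' Named simulation-setting presets
#'
#' Constructs a [scenario_spec()] for one of the eight named simulation
#' settings:
#' \describe{
#'   \item{1}{Base case: continuous covariate, coefficients
#'     `(1, 0.5, 0.3, 0)`, residual SD 1, normal random effects.}
#'   \item{2}{Base case plus small-study selection: 20% of studies ranked
#'     lowest on the size/effect composite are dropped.}
#'   \item{3}{Residual SD varies across studies (mean 1, SD 0.5).}
#'   \item{4}{Skew-normal random effects (skewness 1, kurtosis 4) on all
#'     components.}
#'   \item{5}{Interaction focus, continuous covariate, coefficients
#'     `(1, 1, 0.5, 0.4)`.}
#'   \item{6}{As 5 with a binary covariate at fixed prevalence 0.5
#'     (binary-by-binary interaction).}
#'   \item{7}{As 6 with per-study covariate prevalence drawn uniformly on
#'     `[0, 1]` (single-sex-study scenario).}
#'   \item{8}{As 6 with additional heterogeneity I² = 50% on both the
#'     covariate and the interaction component.}
#' }
#' The intercept and exposure I² levels are cell parameters and are passed
#' separately.
#'
#' @param setting Integer 1–8.
#' @param n_studies,mean_study_size Study-count and mean-size cell
#'   parameters.
#' @param i2_intercept,i2_exposure Intercept and exposure heterogeneity for
#'   the cell.
#' @param seed Optional replication seed.
#' @return A `scenario_spec`.
#' @export
setting_preset <- function(setting, n_studies, mean_study_size,
                           i2_intercept = 0, i2_exposure = 0, seed = NULL) {
  setting <- as.integer(setting)
  if (!setting %in% 1:8) stop("`setting` must be in 1..8", call. = FALSE)
  base <- list(n_studies = n_studies, mean_study_size = mean_study_size,
               i2_intercept = i2_intercept, i2_exposure = i2_exposure,
               seed = seed)
  main <- list(gamma0 = 1, gamma1 = 0.5, gamma2 = 0.3, gamma3 = 0)
  intn <- list(gamma0 = 1, gamma1 = 1, gamma2 = 0.5, gamma3 = 0.4)
  extra <- switch(setting,
    main,                                                   # 1
    c(main, list(selection_fraction = 0.2)),                # 2
    c(main, list(sigma_sd = 0.5)),                          # 3
    c(main, list(re_distribution = "skew_normal")),         # 4
    intn,                                                   # 5
    c(intn, list(covariate_kind = "binary")),               # 6
    c(intn, list(covariate_kind = "binary",
                 covariate_prevalence_varying = TRUE)),     # 7
    c(intn, list(covariate_kind = "binary",
                 i2_covariate = 0.5, i2_interaction = 0.5)) # 8
  )
  spec <- do.call(scenario_spec, c(base, extra))
  spec$setting <- setting
  spec
}

# Analysis target implied by a setting: the exposure main effect for the
# main-effect settings, the interaction for the interaction settings.
setting_target <- function(setting) {
  if (setting <= 4) "exposure" else "interaction"
}

# Null value for the power calculation: 0 for main-effect settings,
# 0.2 for interaction settings.
setting_null_value <- function(setting) {
  if (setting <= 4) 0 else 0.2
}
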