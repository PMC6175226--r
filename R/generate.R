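#' Generate a synthetic IPD meta-analysis dataset
#'
#' Realizes one IPD dataset from a [scenario_spec()].  For each study `j`
#' the generator draws a size, centred random effects `u0j..u3j` (scaled so
#' each component's between-study variance matches its target I² against
#' the residual variance), a residual SD, and, for a binary covariate, a
#' prevalence.  Patient rows are then
#' \deqn{y_{ij} = (\gamma_0 + u_{0j}) + (\gamma_1 + u_{1j})\,group_{ij} +
#'   (\gamma_2 + u_{2j})\,x_{ij} + (\gamma_3 + u_{3j})\,group_{ij} x_{ij} +
#'   \epsilon_{ij},}
#' with `group ~ Bernoulli(exposure_prob)`, `x ~ N(0,1)` (continuous) or
#' `Bernoulli(p_j)` (binary) and `eps ~ N(0, sigma_j^2)`.
#'
#' The result is a data frame with columns `study_id`, `y`, `group`, `x`
#' and attributes `scenario` (the generating spec) and `studies` (a data
#' frame of per-study truths: size, realized random effects, true exposure
#' and interaction slopes, residual SD, covariate prevalence), so
#' downstream metric computations always know the generating truth.
#'
#' When `spec$seed` is set the dataset is bit-reproducible; otherwise the
#' current RNG state is used.
#'
#' @param spec A [scenario_spec()].
#' @return An object of classes `ipd_dataset` and `data.frame`.
#' @export
generate_ipd <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  k <- spec$n_studies
  sizes <- draw_study_sizes(k, spec$mean_study_size, spec$size_range)
  sigma2 <- spec$sigma_mean^2
  tau2 <- c(intercept = i2_to_tau2(spec$i2_intercept, sigma2),
            exposure = i2_to_tau2(spec$i2_exposure, sigma2),
            covariate = i2_to_tau2(spec$i2_covariate, sigma2),
            interaction = i2_to_tau2(spec$i2_interaction, sigma2))
  u <- draw_random_effects(k, tau2, spec$re_distribution,
                           spec$re_skewness, spec$re_kurtosis,
                           spec$kurtosis_convention)

  if (spec$sigma_sd == 0) {
    sigma_j <- rep(spec$sigma_mean, k)
  } else {
    # truncated-normal residual SD: redraw until above the floor
    sigma_j <- stats::rnorm(k, spec$sigma_mean, spec$sigma_sd)
    while (any(bad <- sigma_j < 0.05))
      sigma_j[bad] <- stats::rnorm(sum(bad), spec$sigma_mean, spec$sigma_sd)
  }

  prev <- rep(NA_real_, k)
  if (spec$covariate_kind == "binary")
    prev <- if (spec$covariate_prevalence_varying) stats::runif(k)
            else rep(0.5, k)

  beta0 <- spec$gamma0 + u[, "intercept"]
  beta1 <- spec$gamma1 + u[, "exposure"]
  beta2 <- spec$gamma2 + u[, "covariate"]
  beta3 <- spec$gamma3 + u[, "interaction"]

  rows <- vector("list", k)
  for (j in seq_len(k)) {
    n <- sizes[j]
    group <- stats::rbinom(n, 1, spec$exposure_prob)
    x <- if (spec$covariate_kind == "continuous") stats::rnorm(n)
         else stats::rbinom(n, 1, prev[j])
    if (spec$centre_covariate && spec$covariate_kind == "continuous")
      x <- x - mean(x)
    eps <- stats::rnorm(n, 0, sigma_j[j])
    y <- beta0[j] + beta1[j] * group + beta2[j] * x +
      beta3[j] * group * x + eps
    rows[[j]] <- data.frame(study_id = j, y = y, group = group, x = x)
  }
  out <- do.call(rbind, rows)
  studies <- data.frame(study_id = seq_len(k), n_patients = sizes,
                        u0 = u[, "intercept"], u1 = u[, "exposure"],
                        u2 = u[, "covariate"], u3 = u[, "interaction"],
                        beta1_true = beta1, beta3_true = beta3,
                        sigma_j = sigma_j, covariate_prevalence = prev)
  structure(out, scenario = spec, studies = studies,
            class = c("ipd_dataset", "data.frame"))
}

#' Per-study truth table of an IPD dataset
#'
#' @param dataset An `ipd_dataset`.
#' @return Data frame with one row per study: size, realized random
#'   effects, true exposure/interaction slopes, residual SD and covariate
#'   prevalence.
#' @export
study_truth <- function(dataset) {
  st <- attr(dataset, "studies")
  if (is.null(st)) stop("dataset carries no per-study truth table",
                        call. = FALSE)
  st
}

#' @export
print.ipd_dataset <- function(x, ...) {
  st <- attr(x, "studies")
  cat("IPD dataset:", nrow(x), "patients in",
      length(unique(x$study_id)), "studies\n")
  if (!is.null(st))
    cat(sprintf("  study sizes %d-%d; true exposure effects in [%.3f, %.3f]\n",
                min(st$n_patients), max(st$n_patients),
                min(st$beta1_true), max(st$beta1_true)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
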