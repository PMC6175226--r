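#' One-stage mixed-model specifications
#'
#' The one-stage model family varies how the intercept and covariate enter
#' (a single common fixed coefficient, one fixed coefficient per study, or
#' a study-level random effect) around a random exposure effect:
#' \describe{
#'   \item{a}{common fixed intercept, random exposure effect, common fixed
#'     covariate effect;}
#'   \item{b}{fixed study-specific intercepts, random exposure effect,
#'     fixed study-specific covariate effects;}
#'   \item{c}{random study intercept, random exposure effect, fixed
#'     study-specific covariate effects — the random intercept and
#'     exposure effects share an unstructured 2x2 covariance;}
#'   \item{e}{model b plus a random interaction effect;}
#'   \item{f}{model c plus a random interaction effect;}
#'   \item{g}{random intercept, random exposure, random covariate and
#'     random interaction effects, independent covariance structure.}
#' }
#' The interaction term is absent by default for models a–c and is switched
#' on (as a common fixed effect) by the harness for interaction-focused
#' settings.
#'
#' @param model_id One of `"a"`, `"b"`, `"c"`, `"e"`, `"f"`, `"g"`.
#' @param interaction Override the interaction treatment: `"absent"`,
#'   `"common_fixed"` or `"random"`.  Defaults to the registry value
#'   (absent for a–c, random for e–g).
#' @param random_cov_structure `"unstructured"` (default where both the
#'   intercept and exposure are random, i.e. models c and f) or
#'   `"independent"`.  Model g defaults to independent across all its
#'   random terms; full unstructured covariance there rarely converges.
#' @return A list of class `onestage_spec`.
#' @export
onestage_model_spec <- function(model_id = c("a", "b", "c", "e", "f", "g"),
                                interaction = NULL,
                                random_cov_structure = NULL) {
  model_id <- match.arg(model_id)
  reg <- switch(model_id,
    a = list(intercept = "common_fixed", covariate = "common_fixed",
             interaction = "absent", structure = "independent"),
    b = list(intercept = "study_fixed", covariate = "study_fixed",
             interaction = "absent", structure = "independent"),
    c = list(intercept = "random", covariate = "study_fixed",
             interaction = "absent", structure = "unstructured"),
    e = list(intercept = "study_fixed", covariate = "study_fixed",
             interaction = "random", structure = "independent"),
    f = list(intercept = "random", covariate = "study_fixed",
             interaction = "random", structure = "unstructured"),
    g = list(intercept = "random", covariate = "random",
             interaction = "random", structure = "independent"))
  if (!is.null(interaction)) {
    interaction <- match.arg(interaction,
                             c("absent", "common_fixed", "random"))
    reg$interaction <- interaction
  }
  if (!is.null(random_cov_structure))
    reg$structure <- match.arg(random_cov_structure,
                               c("unstructured", "independent"))
  structure(list(model_id = model_id, intercept = reg$intercept,
                 exposure = "random", covariate = reg$covariate,
                 interaction = reg$interaction,
                 random_cov_structure = reg$structure),
            class = "onestage_spec")
}

# Build the lme4 formula implied by a model spec.  `gx` is the
# precomputed group*x product so the interaction can appear in random
# terms with a stable coefficient name.
onestage_formula <- function(spec) {
  fixed <- switch(spec$intercept,
                  common_fixed = "1",
                  study_fixed = "0 + fstudy",
                  random = "1")
  fixed <- c(fixed, "group")
  fixed <- c(fixed, switch(spec$covariate,
                           common_fixed = "x",
                           study_fixed = "fstudy:x",
                           random = "x"))
  if (spec$interaction != "absent") fixed <- c(fixed, "gx")
  ranef <- character()
  if (spec$intercept == "random" &&
      spec$random_cov_structure == "unstructured") {
    ranef <- c(ranef, "(1 + group | fstudy)")
  } else {
    if (spec$intercept == "random") ranef <- c(ranef, "(1 | fstudy)")
    ranef <- c(ranef, "(0 + group | fstudy)")
  }
  if (spec$covariate == "random") ranef <- c(ranef, "(0 + x | fstudy)")
  if (spec$interaction == "random") ranef <- c(ranef, "(0 + gx | fstudy)")
  stats::as.formula(paste("y ~", paste(c(fixed, ranef), collapse = " + ")))
}

#' Fit a one-stage mixed-effects IPD model
#'
#' Builds the design implied by the model specification (study-fixed terms
#' as indicator coding with no global intercept, random terms grouped by
#' study) and fits it by maximum likelihood with \pkg{lme4}.  Inference on
#' the target coefficient is Wald: `estimate +/- 1.96 * se`.
#'
#' Convergence is defined as: the optimizer reported success, no lme4
#' convergence warning survived one automatic refit with a different
#' optimizer (bobyqa), and the target coefficient has a finite positive
#' standard error.  A boundary (singular) fit — a variance component
#' estimated at zero — is a valid ML solution and counts as converged;
#' likelihood software in routine use reports these as converged fits.
#' The exception is an unstructured random-effects covariance estimated
#' with non-degenerate variances but a correlation at the +/-1 boundary:
#' there the correlation parameter diverges in the unconstrained
#' parameterization inference relies on, and the fit is recorded as
#' non-converged.
#' Studies whose study-specific covariate column is inestimable (a constant
#' covariate within the study) are handled by dropping the rank-deficient
#' columns, with a note recorded in the result.
#'
#' @param dataset An `ipd_dataset` (>= 2 studies).
#' @param spec An [onestage_model_spec()].
#' @param target `"exposure"` (the `group` coefficient) or `"interaction"`
#'   (the `group:x` coefficient; requires a model with an interaction
#'   term).
#' @param reml Fit by REML instead of ML (default `FALSE`, plain ML).
#' @return A `fit_result`: model id, target, estimate, `se`, 95% CI,
#'   convergence flag, estimated variance components, studies used, notes.
#' @export
fit_onestage <- function(dataset, spec, target = c("exposure", "interaction"),
                         reml = FALSE) {
  stopifnot(inherits(spec, "onestage_spec"))
  target <- match.arg(target)
  k <- length(unique(dataset$study_id))
  if (k < 2)
    stop("one-stage IPD meta-analysis needs at least 2 studies",
         call. = FALSE)
  if (target == "interaction" && spec$interaction == "absent")
    stop("interaction target requires a model with an interaction term",
         call. = FALSE)
  df <- data.frame(y = dataset$y, group = dataset$group, x = dataset$x,
                   gx = dataset$group * dataset$x,
                   fstudy = factor(dataset$study_id))
  form <- onestage_formula(spec)
  coef_name <- if (target == "exposure") "group" else "gx"

  fit_once <- function(optimizer) {
    msgs <- character()
    fit <- withCallingHandlers(
      tryCatch(
        lme4::lmer(form, data = df, REML = reml,
                   control = lme4::lmerControl(optimizer = optimizer,
                                               calc.derivs = TRUE)),
        error = function(e) e),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    list(fit = fit, msgs = msgs)
  }

  is_conv_warning <- function(msgs) {
    bad <- grepl("failed to converge|convergence code|pwrssUpdate|Downdated|unable to evaluate|degenerate",
                 msgs, ignore.case = TRUE)
    # boundary/singular messages are informational, not failures
    bad & !grepl("boundary \\(singular\\)", msgs)
  }

  res <- fit_once("nloptwrap")
  failed <- inherits(res$fit, "error") || any(is_conv_warning(res$msgs))
  if (failed) {
    res2 <- fit_once("bobyqa")
    if (!inherits(res2$fit, "error") && !any(is_conv_warning(res2$msgs)))
      res <- res2
  }

  notes <- unique(res$msgs)
  if (inherits(res$fit, "error"))
    return(fit_result(spec$model_id, target, NA_real_, NA_real_,
                      converged = FALSE, n_studies_used = k,
                      notes = c(notes, conditionMessage(res$fit))))
  fit <- res$fit
  beta <- lme4::fixef(fit)
  if (!coef_name %in% names(beta))
    return(fit_result(spec$model_id, target, NA_real_, NA_real_,
                      converged = FALSE, n_studies_used = k,
                      notes = c(notes, "target coefficient dropped")))
  est <- unname(beta[coef_name])
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))[
    match(coef_name, names(beta))]), error = function(e) NA_real_)
  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
  converged <- opt_ok && !any(is_conv_warning(notes)) &&
    is.finite(est) && is.finite(se) && se > 0

  # Degenerate unstructured covariance: |rho| estimated at the +/-1
  # boundary with non-degenerate variances means the correlation
  # parameter diverges in the unconstrained parameterization optimizers
  # and Wald inference rely on — recorded as non-convergence.  A plain
  # zero-variance boundary is a valid ML solution and stays converged.
  if (converged && spec$intercept == "random" &&
      spec$random_cov_structure == "unstructured") {
    vc_g <- lme4::VarCorr(fit)$fstudy
    rho <- attr(vc_g, "correlation")[1, 2]
    if (all(diag(vc_g) > 1e-8) && is.finite(rho) && abs(rho) > 0.999) {
      converged <- FALSE
      notes <- c(notes, "degenerate random-effects correlation (|rho| = 1)")
    }
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- stats::setNames(vc$vcov[is.na(vc$var2)],
                          paste0(vc$grp[is.na(vc$var2)], ".",
                                 vc$var1[is.na(vc$var2)]))
  fit_result(spec$model_id, target, est, se, converged = converged,
             tau2_estimates = tau2, n_studies_used = k, notes = notes)
}

# Constructor for the per-fit record shared by one- and two-stage fitters.
fit_result <- function(model_id, target, estimate, se, converged,
                       tau2_estimates = numeric(), n_studies_used = NA,
                       notes = character()) {
  z <- stats::qnorm(0.975)
  structure(list(model_id = model_id, target = target,
                 estimate = estimate, se = se,
                 ci_low = estimate - z * se, ci_high = estimate + z * se,
                 converged = converged, tau2_estimates = tau2_estimates,
                 n_studies_used = n_studies_used, notes = notes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("model %s [%s]: estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], %s\n",
              x$model_id, x$target, x$estimate, x$se, x$ci_low, x$ci_high,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}
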