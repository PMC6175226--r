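# Fleishman power-method coefficients: Y = a + bZ + cZ^2 + dZ^3 with
# Z ~ N(0,1), constrained to mean 0 (a = -c) and variance 1, matching a
# target skewness and excess kurtosis.  Solved numerically by Newton
# iteration on the three moment equations; results are cached per target.
.fleishman_cache <- new.env(parent = emptyenv())

fleishman_equations <- function(p, skewness, kurtosis_excess) {
  b <- p[1]; cc <- p[2]; d <- p[3]
  c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
    2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skewness,
    24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
            d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) -
      kurtosis_excess)
}

#' Fleishman polynomial coefficients for a target skewness and kurtosis
#'
#' Solves the power-method moment equations so that
#' `a + b Z + c Z^2 + d Z^3` (with `a = -c`, `Z` standard normal) has mean
#' 0, variance 1 and the requested standardized third and fourth moments.
#' Targets outside the feasible region of the cubic transform (roughly
#' `excess kurtosis >= 1.64 * skewness^2 - 1.23`) are rejected.
#'
#' @param skewness Target standardized skewness.
#' @param kurtosis_excess Target excess kurtosis (normal = 0).
#' @return Named numeric vector `(a, b, c, d)`.
#' @export
fleishman_coefficients <- function(skewness, kurtosis_excess) {
  key <- paste(signif(skewness, 12), signif(kurtosis_excess, 12))
  if (!is.null(.fleishman_cache[[key]])) return(.fleishman_cache[[key]])
  p <- c(0.9, 0.15 * sign(skewness + (skewness == 0)), 0.03)
  ok <- FALSE
  for (iter in 1:200) {
    f <- fleishman_equations(p, skewness, kurtosis_excess)
    if (max(abs(f)) < 1e-12) { ok <- TRUE; break }
    # finite-difference Jacobian
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      ph <- p; ph[j] <- ph[j] + h
      J[, j] <- (fleishman_equations(ph, skewness, kurtosis_excess) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    # damped Newton: halve until residual decreases
    lambda <- 1
    repeat {
      pn <- p - lambda * step
      fn <- fleishman_equations(pn, skewness, kurtosis_excess)
      if (sum(fn^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    p <- pn
  }
  if (!ok) {
    f <- fleishman_equations(p, skewness, kurtosis_excess)
    if (max(abs(f)) > 1e-8)
      stop(sprintf(paste("(skewness = %g, excess kurtosis = %g) is outside",
                         "the feasible region of the cubic transform"),
                   skewness, kurtosis_excess), call. = FALSE)
  }
  out <- c(a = -p[2], b = p[1], c = p[2], d = p[3])
  .fleishman_cache[[key]] <- out
  out
}

#' Draw centred between-study random effects
#'
#' Draws `k` independent realizations of up to four random-effects
#' components (intercept, exposure, covariate, interaction), each with mean
#' 0 and variance equal to its `tau2` entry.  Components are independent
#' across levels; the generator never imposes a cross-level correlation
#' (the analysis models may still estimate one).  Under
#' `distribution = "skew_normal"` each non-degenerate component is a
#' Fleishman cubic transform of a standard normal, rescaled to its target
#' variance, so the standardized skewness and kurtosis match the requested
#' targets.
#'
#' Draws use the current RNG state.
#'
#' @param k Number of studies.
#' @param tau2 Named (or positional) numeric vector of between-study
#'   variances; names among `intercept`, `exposure`, `covariate`,
#'   `interaction`.  Zero entries yield exactly-zero columns.
#' @param distribution `"normal"` or `"skew_normal"`.
#' @param skewness,kurtosis Moment targets for `"skew_normal"`;
#'   `kurtosis` is interpreted per `kurtosis_convention`.
#' @param kurtosis_convention `"total"` (normal = 3) or `"excess"`.
#' @return A `k` x `length(tau2)` matrix of realized random effects.
#' @export
draw_random_effects <- function(k, tau2,
                                distribution = c("normal", "skew_normal"),
                                skewness = 1, kurtosis = 4,
                                kurtosis_convention = c("total", "excess")) {
  distribution <- match.arg(distribution)
  kurtosis_convention <- match.arg(kurtosis_convention)
  if (any(tau2 < 0)) stop("`tau2` entries must be non-negative",
                          call. = FALSE)
  if (is.null(names(tau2)))
    names(tau2) <- c("intercept", "exposure", "covariate",
                     "interaction")[seq_along(tau2)]
  u <- matrix(0, nrow = k, ncol = length(tau2),
              dimnames = list(NULL, names(tau2)))
  excess <- if (kurtosis_convention == "total") kurtosis - 3 else kurtosis
  for (comp in seq_along(tau2)) {
    t2 <- tau2[comp]
    if (t2 == 0) next
    if (distribution == "normal") {
      u[, comp] <- stats::rnorm(k, 0, sqrt(t2))
    } else {
      cf <- fleishman_coefficients(skewness, excess)
      z <- stats::rnorm(k)
      u[, comp] <- sqrt(t2) *
        (cf["a"] + cf["b"] * z + cf["c"] * z^2 + cf["d"] * z^3)
    }
  }
  u
}
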