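# Shared fixtures built in code.

# A study_estimates table from raw vectors.
make_estimates <- function(coefs, vars, ids = seq_along(coefs),
                           n = 100L, estimable = TRUE) {
  structure(data.frame(study_id = ids, coef = coefs, var = vars, n = n,
                       estimable = estimable),
            class = c("study_estimates", "data.frame"))
}

# A noise-free deterministic IPD dataset (exact linear relationship) with
# a minimal truth table so filters/fitters accept it.
make_exact_ipd <- function(k = 3, n = 20, g0 = 1, g1 = 0.5, g2 = 0.3) {
  rows <- do.call(rbind, lapply(seq_len(k), function(j) {
    group <- rep(c(0, 1), length.out = n)
    x <- seq(-1, 1, length.out = n) + 0.1 * j
    data.frame(study_id = j, y = g0 + g1 * group + g2 * x,
               group = group, x = x)
  }))
  studies <- data.frame(study_id = seq_len(k), n_patients = n,
                        u0 = 0, u1 = 0, u2 = 0, u3 = 0,
                        beta1_true = g1, beta3_true = 0,
                        sigma_j = 1, covariate_prevalence = NA_real_)
  structure(rows, studies = studies,
            class = c("ipd_dataset", "data.frame"))
}

# Brute-force REML tau2 oracle: dense grid search on the restricted
# log-likelihood, independent of the optimize()-based implementation.
grid_reml_tau2 <- function(yi, vi, upper = NULL, n_grid = 400001) {
  if (is.null(upper)) upper <- max(1e-6, 10 * stats::var(yi), 10 * max(vi))
  ll <- function(t2) {
    w <- 1 / (vi + t2)
    th <- sum(w * yi) / sum(w)
    -0.5 * (sum(log(vi + t2)) + log(sum(w)) + sum(w * (yi - th)^2))
  }
  ts <- seq(0, upper, length.out = n_grid)
  vals <- vapply(ts, ll, numeric(1))
  ts[which.max(vals)]
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
sample_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
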