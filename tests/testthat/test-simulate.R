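test_that("i2_to_tau2 matches the algebra and round-trips", {
  expect_equal(i2_to_tau2(0.5, 1), 1)
  expect_equal(i2_to_tau2(0, 1), 0)
  expect_equal(i2_to_tau2(2 / 3, 1), 2)
  # round-trip I2 = tau2/(tau2 + sigma2) across a grid
  for (i2 in c(0, 0.1, 1 / 3, 0.5, 0.67, 0.9)) {
    for (s2 in c(0.25, 1, 4)) {
      t2 <- i2_to_tau2(i2, s2)
      expect_equal(t2 / (t2 + s2), i2)
    }
  }
  expect_error(i2_to_tau2(1, 1), "\\[0, 1\\)")
  expect_error(i2_to_tau2(0.5, 0), "positive")
})

test_that("study sizes are uniform integers around the mean", {
  set.seed(11)
  s <- draw_study_sizes(10, 500)
  expect_length(s, 10)
  expect_true(all(s == round(s)))
  expect_true(all(s >= 250 & s <= 750))
  big <- draw_study_sizes(10000, 500)
  expect_lt(abs(mean(big) - 500) / 500, 0.01)
  expect_error(draw_study_sizes(1, 500), "at least 2")
})

test_that("random-effects draws hit their moment targets", {
  set.seed(21)
  expect_true(all(draw_random_effects(50, c(0, 0, 0, 0)) == 0))
  u <- draw_random_effects(1e6, c(exposure = 1), "normal")
  expect_lt(abs(var(u[, 1]) - 1), 0.01)
  expect_lt(abs(sample_skewness(u[, 1])), 0.01)
  us <- draw_random_effects(1e6, c(exposure = 1), "skew_normal",
                            skewness = 1, kurtosis = 4)
  expect_lt(abs(mean(us[, 1])), 0.01)
  expect_lt(abs(var(us[, 1]) - 1), 0.02)
  expect_lt(abs(sample_skewness(us[, 1]) - 1), 0.05)
  expect_lt(abs(sample_kurtosis(us[, 1]) - 4), 0.2)
  expect_error(draw_random_effects(10, c(1), "skew_normal",
                                   skewness = 4, kurtosis = 3),
               "feasible")
})

test_that("kurtosis convention switch changes the fourth-moment target", {
  set.seed(22)
  u <- draw_random_effects(5e5, c(exposure = 1), "skew_normal",
                           skewness = 1, kurtosis = 4,
                           kurtosis_convention = "excess")
  expect_lt(abs(sample_kurtosis(u[, 1]) - 7), 0.6)
})

test_that("setting presets carry the stated parameterizations", {
  s1 <- setting_preset(1, 10, 500)
  expect_equal(unlist(s1[c("gamma0", "gamma1", "gamma2", "gamma3")]),
               c(gamma0 = 1, gamma1 = 0.5, gamma2 = 0.3, gamma3 = 0))
  expect_equal(s1$selection_fraction, 0)
  expect_equal(setting_preset(2, 10, 500)$selection_fraction, 0.2)
  expect_equal(setting_preset(3, 10, 500)$sigma_sd, 0.5)
  expect_equal(setting_preset(4, 10, 500)$re_distribution, "skew_normal")
  for (s in 5:8) {
    sp <- setting_preset(s, 10, 500)
    expect_equal(unlist(sp[c("gamma0", "gamma1", "gamma2", "gamma3")]),
                 c(gamma0 = 1, gamma1 = 1, gamma2 = 0.5, gamma3 = 0.4))
  }
  expect_equal(setting_preset(6, 10, 500)$covariate_kind, "binary")
  expect_true(setting_preset(7, 10, 500)$covariate_prevalence_varying)
  s8 <- setting_preset(8, 10, 500)
  expect_equal(c(s8$i2_covariate, s8$i2_interaction), c(0.5, 0.5))
})

test_that("generated datasets have the stated structure", {
  ds <- generate_ipd(setting_preset(1, 10, 500, seed = 301))
  st <- study_truth(ds)
  expect_equal(nrow(st), 10)
  expect_true(all(st$n_patients >= 250 & st$n_patients <= 750))
  expect_true(all(sort(unique(ds$study_id)) == 1:10))
  expect_lt(abs(mean(ds$group) - 0.5), 0.02)
  expect_true(all(ds$group %in% 0:1))
  expect_equal(st$sigma_j, rep(1, 10))   # sigma_sd = 0 => exact
  # no heterogeneity: all true slopes equal the means
  expect_equal(st$beta1_true, rep(0.5, 10))
})

test_that("identical spec (incl. seed) gives bit-identical data", {
  sp <- setting_preset(4, 6, 100, 0.5, 0.5, seed = 99)
  d1 <- generate_ipd(sp)
  d2 <- generate_ipd(sp)
  expect_identical(d1$y, d2$y)
  expect_identical(study_truth(d1), study_truth(d2))
})

test_that("OLS recovers the coefficients when heterogeneity is absent", {
  sp <- scenario_spec(n_studies = 2, mean_study_size = 250000,
                      gamma0 = 1, gamma1 = 0.5, gamma2 = 0.3, seed = 77)
  ds <- generate_ipd(sp)
  fit <- coef(lm(y ~ group + x, data = ds))
  expect_lt(abs(fit["(Intercept)"] - 1), 0.02)
  expect_lt(abs(fit["group"] - 0.5), 0.02)
  expect_lt(abs(fit["x"] - 0.3), 0.02)
})

test_that("heterogeneity round-trips through empirical I2", {
  set.seed(55)
  for (h in c(1 / 3, 0.5)) {
    t2 <- i2_to_tau2(h, 1)
    u <- draw_random_effects(20000, c(exposure = t2), "normal")
    v <- var(0.5 + u[, 1])
    expect_lt(abs(v / (v + 1) - h), 0.02)
  }
})

test_that("varying covariate prevalence spreads across [0,1]", {
  ds <- generate_ipd(setting_preset(7, 40, 100, seed = 7))
  st <- study_truth(ds)
  expect_true(all(st$covariate_prevalence >= 0 &
                    st$covariate_prevalence <= 1))
  expect_gt(max(st$covariate_prevalence), 0.8)
  expect_lt(min(st$covariate_prevalence), 0.2)
  # observed prevalences track the drawn ones and span a wide range
  obs <- tapply(ds$x, ds$study_id, mean)
  expect_gt(max(obs), 0.85)
  expect_lt(min(obs), 0.15)
  expect_lt(max(abs(obs - st$covariate_prevalence)), 0.15)
})

test_that("varying residual SD stays positive and centred near its mean", {
  ds <- generate_ipd(setting_preset(3, 400, 100, seed = 33))
  st <- study_truth(ds)
  expect_true(all(st$sigma_j >= 0.05))
  expect_lt(abs(mean(st$sigma_j) - 1), 0.1)
})

test_that("dataset round-trips through CSV with its truth sidecar", {
  dir <- withr::local_tempdir()
  ds <- generate_ipd(setting_preset(1, 4, 50, seed = 5))
  p <- file.path(dir, "ipd.csv")
  write_ipd(ds, p)
  back <- read_ipd(p)
  expect_equal(back$y, ds$y)
  expect_equal(study_truth(back)$beta1_true, study_truth(ds)$beta1_true)
  expect_equal(attr(back, "scenario")$gamma1, 0.5)
})
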