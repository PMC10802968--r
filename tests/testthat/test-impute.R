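test_that("predictive draws respect the truncation support", {
  d <- simulate_scenario("weibull", 2, 120, 0.1, -3, 0.3, seed = 91)
  fit <- fit_survival_bayes(d, "weibull", control = quick_control(seed = 92))
  cens <- d[d$status == 0, ]
  for (i in seq_len(min(5, nrow(cens)))) {
    dr <- predictive_draws(fit, cens$time[i], x = cens$x[i], seed = 93 + i)
    expect_length(dr, nrow(fit$draws))
    expect_true(all(dr >= cens$time[i]))
  }
})

test_that("a degenerate posterior reduces prediction to the known truncated law", {
  fit <- point_fit_weibull(2, 0.25, n_draws = 10000)
  m <- lifetime_model("weibull", 2, rate = 0.25)
  dr <- predictive_draws(fit, 2, seed = 94)
  expect_equal(median(dr), cond_median(2, m), tolerance = 0.02)
  # c = 0: draws follow the unconditional law
  dr0 <- predictive_draws(fit, 0, seed = 95)
  expect_lt(ks_distance(dr0, function(x) 1 - model_sf(m, x)), 0.02)
  # same for the BS family
  fitb <- point_fit_bs(0.5, 4, n_draws = 10000)
  mb <- lifetime_model("bs", 0.5, scale = 4)
  drb <- predictive_draws(fitb, 4, seed = 96)
  expect_true(all(drb >= 4))
  expect_equal(median(drb), cond_median(4, mb), tolerance = 0.03)
})

test_that("imputation replaces only censored records and preserves structure", {
  d <- simulate_scenario("weibull", 1, 100, 0.15, -1.5, 0.4, seed = 97)
  fit <- point_fit_weibull(1, 0.25, n_draws = 2000)
  fit$covariate <- FALSE
  imp <- impute_censored(d, fit, summary = "median", seed = 98)
  aug <- augmented_data(imp)
  expect_identical(nrow(aug), nrow(d))
  ev <- d$status == 1
  expect_identical(aug$imputed_time[ev], d$time[ev])     # events untouched
  expect_identical(aug$x, d$x)                           # covariates intact
  expect_true(all(aug$was_censored == (d$status == 0)))
  expect_true(all(imp$summaries$imputed >= imp$summaries$time))
  expect_true(all(imp$summaries$draw_mean >= imp$summaries$time))
  # both summaries dominate c; mean vs median ordering is NOT asserted
  imp_mean <- impute_censored(d, fit, summary = "mean", seed = 98)
  expect_true(all(imp_mean$summaries$imputed >= imp_mean$summaries$time))
})

test_that("imputing a fully observed dataset is a warned no-op", {
  d <- tibble::tibble(time = c(1, 2, 3), status = 1)
  fit <- point_fit_weibull(1, 0.5)
  expect_warning(imp <- impute_censored(d, fit), "no censored")
  expect_identical(augmented_data(imp)$imputed_time, d$time)
  expect_identical(nrow(tidy(imp)), 0L)
})

test_that("degenerate-posterior median imputation hits the closed form", {
  d <- tibble::tibble(time = c(1, 2, 4), status = c(1, 0, 0))
  fit <- point_fit_weibull(2, 0.25, n_draws = 4001)
  fit$covariate <- FALSE
  imp <- impute_censored(d, fit, summary = "median", seed = 99)
  m <- lifetime_model("weibull", 2, rate = 0.25)
  closed <- cond_median(c(2, 4), m)
  expect_equal(imp$summaries$imputed, closed, tolerance = 0.03)
  # the closed-form path itself is exact
  expect_equal(cond_median(2, m), sqrt(log(2) / 0.25 + 4), tolerance = 1e-12)
})

test_that("the BS unconditional-median shortcut ignores truncation by design", {
  d <- tibble::tibble(time = c(2, 6), status = c(1, 0))
  fit <- point_fit_bs(0.5, 4, n_draws = 500)
  fit$covariate <- FALSE
  generic <- impute_censored(d, fit, summary = "median", seed = 100)
  shortcut <- impute_censored(d, fit, summary = "median", seed = 100,
                              bs_median_shortcut = TRUE)
  expect_equal(shortcut$summaries$imputed, 4)     # the scale itself
  expect_gte(generic$summaries$imputed, 6)        # truncated median >= c
})

test_that("predictive uncertainty grows with the censoring fraction", {
  fit <- point_fit_weibull(2, exp(-3), n_draws = 3000)
  low <- simulate_scenario("weibull", 2, 200, 0.02, -3, 0.3, seed = 101)
  high <- simulate_scenario("weibull", 2, 200, 0.20, -3, 0.3, seed = 101)
  imp_low <- impute_censored(low, fit, seed = 102)
  imp_high <- impute_censored(high, fit, seed = 102)
  expect_gt(mean(draw_band(imp_high)$iqr), mean(draw_band(imp_low)$iqr))
  expect_gt(nrow(imp_high$summaries), nrow(imp_low$summaries))
})
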