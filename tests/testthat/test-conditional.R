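models_under_test <- function() {
  list(w05 = lifetime_model("weibull", 0.5, rate = 0.4),
       w1  = lifetime_model("weibull", 1, rate = 0.25),
       w2  = lifetime_model("weibull", 2, rate = 0.25),
       bs  = lifetime_model("bs", 0.5, scale = 4))
}

test_that("truncated density normalizes over [c, Inf) and matches f/S(c)", {
  for (m in models_under_test()) {
    for (c0 in c(0, model_quantile(m, 0.5), model_quantile(m, 0.95))) {
      int <- stats::integrate(function(t) cond_pdf(t, c0, m),
                              max(c0, 1e-12), model_quantile(m, 1 - 1e-13),
                              rel.tol = 1e-12)$value
      expect_equal(int, 1, tolerance = 1e-8)
    }
    # c = 0 reduces to the unconditional density
    t <- seq(0.5, 6, length.out = 20)
    expect_equal(cond_pdf(t, 0, m), model_pdf(m, t), tolerance = 1e-12)
  }
  m <- models_under_test()$w2
  expect_equal(cond_pdf(1, 2, m), 0)  # below the truncation point
})

test_that("exponential truncation is memoryless", {
  m <- lifetime_model("weibull", 1, rate = 0.25)
  t <- seq(3, 15, length.out = 30)
  expect_equal(cond_pdf(t, 3, m), model_pdf(m, t - 3), tolerance = 1e-12)
  cs <- c(0, 1, 2, 7)
  expect_equal(cond_mean(cs, m) - cs, rep(4, 4), tolerance = 1e-12)
})

test_that("truncated means take closed values and agree with a Monte-Carlo oracle", {
  m1 <- lifetime_model("weibull", 1, rate = 0.25)
  expect_equal(cond_mean(2, m1), 6)
  # c = 0 recovers the unconditional mean for every family
  for (m in models_under_test()) {
    expect_equal(cond_mean(0, m), model_mean(m), tolerance = 1e-7)
  }
  # brute-force truncated sampling oracle, Weibull shape 2
  m2 <- lifetime_model("weibull", 2, rate = 0.25)
  withr::with_seed(21, {
    draws <- model_rng(m2, 2e6)
    kept <- draws[draws >= 3]
    se <- stats::sd(kept) / sqrt(length(kept))
    expect_lt(abs(cond_mean(3, m2) - mean(kept)), 3 * se)
  })
  # and a BS oracle
  mb <- lifetime_model("bs", 0.5, scale = 4)
  withr::with_seed(22, {
    draws <- model_rng(mb, 2e6)
    kept <- draws[draws >= 4]
    se <- stats::sd(kept) / sqrt(length(kept))
    expect_lt(abs(cond_mean(4, mb) - mean(kept)), 3 * se)
  })
})

test_that("truncated medians match the closed forms and the generic inversion", {
  m1 <- lifetime_model("weibull", 1, rate = 0.25)
  expect_equal(cond_median(2, m1), 2 + 4 * log(2))
  m2 <- lifetime_model("weibull", 2, rate = 0.25)
  expect_equal(cond_median(0, m2), sqrt(log(2) / 0.25))
  expect_equal(cond_median(0, lifetime_model("bs", 0.5, scale = 4)), 4)
  # generic inversion S^{-1}(0.5 S(c)) reproduces the closed form on a grid
  for (shape in c(0.5, 1, 2)) {
    for (rate in c(0.05, 0.25, 1)) {
      m <- lifetime_model("weibull", shape, rate = rate)
      for (c0 in c(0, 1, 3)) {
        generic <- model_quantile(m, 1 - 0.5 * model_sf(m, max(c0, 1e-300)))
        if (c0 == 0) generic <- model_quantile(m, 0.5)
        expect_equal(cond_median(c0, m), generic, tolerance = 1e-9)
      }
    }
  }
})

test_that("truncated summaries are nondecreasing in c and dominate c", {
  cs <- seq(0, 8, length.out = 17)
  for (m in models_under_test()) {
    mn <- cond_mean(cs, m)
    md <- cond_median(cs, m)
    expect_true(all(diff(mn) > -1e-9))
    expect_true(all(diff(md) > -1e-9))
    expect_true(all(mn >= cs))
    expect_true(all(md >= cs))
  }
})

test_that("truncated sampling is supported on [c, Inf) and follows the analytic law", {
  m2 <- lifetime_model("weibull", 2, rate = 0.25)
  mb <- lifetime_model("bs", 0.5, scale = 4)
  for (spec in list(list(m = m2, c = 2), list(m = mb, c = 4),
                    list(m = m2, c = 0))) {
    draws <- rtrunc(1e4, spec$c, spec$m, seed = 31)
    expect_true(all(draws >= spec$c))
    expect_identical(draws, rtrunc(1e4, spec$c, spec$m, seed = 31))
  }
  draws <- rtrunc(1e6, 2, m2, seed = 32)
  expect_equal(median(draws), cond_median(2, m2), tolerance = 0.005)
  # KS against the analytic truncated CDF
  d5 <- rtrunc(1e5, 2, m2, seed = 33)
  cdf <- function(x) 1 - model_sf(m2, x) / model_sf(m2, 2)
  expect_lt(ks_distance(d5, cdf), 0.01)
  db <- rtrunc(1e5, 4, mb, seed = 34)
  cdfb <- function(x) 1 - model_sf(mb, x) / model_sf(mb, 4)
  expect_lt(ks_distance(db, cdfb), 0.01)
})
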