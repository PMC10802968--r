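test_that("Weibull PH forms satisfy their defining identities", {
  # survival at the origin and the forced exponential median
  expect_equal(sweibull_ph(1e-12, shape = 1, rate = 0.25), 1, tolerance = 1e-9)
  expect_equal(sweibull_ph(4 * log(2), shape = 1, rate = 0.25), 0.5)
  # t at unit cumulative hazard: S = exp(-1)
  expect_equal(sweibull_ph(0.0498^(-1 / 2), shape = 2, rate = 0.0498),
               exp(-1))
  # hazard * survival = density, pointwise
  t <- seq(0.1, 12, length.out = 60)
  for (par in list(c(0.5, 0.4), c(1, 0.25), c(2, 0.05))) {
    expect_equal(hweibull_ph(t, par[1], par[2]) * sweibull_ph(t, par[1], par[2]),
                 dweibull_ph(t, par[1], par[2]), tolerance = 1e-10)
  }
  # PH rate <-> AFT scale round trip
  expect_equal(aft_scale(2, 0.25)^(-2), 0.25)
  expect_error(dweibull_ph(1, shape = -1, rate = 1), "positive")
  expect_error(hweibull_ph(-1, shape = 1, rate = 1), "positive")
})

test_that("BS density normalizes and matches the normal-transform representation", {
  f <- function(t) dbisa(t, shape = 0.5, scale = 4)
  expect_equal(stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value, 1,
               tolerance = 1e-8)
  # pdf = d/dt CDF by central finite differences at t = scale
  h <- 1e-5
  num_deriv <- (pbisa(4 + h, 0.5, 4) - pbisa(4 - h, 0.5, 4)) / (2 * h)
  expect_equal(dbisa(4, 0.5, 4), num_deriv, tolerance = 1e-6)
  # phi(z) |dz/dt| with the change of variables written out independently
  z <- (sqrt(4 / 4) - sqrt(4 / 4)) / 0.5
  dzdt <- (4 + 4) / (2 * 0.5 * sqrt(4) * 4^1.5)
  expect_equal(dbisa(4, 0.5, 4), stats::dnorm(z) * dzdt, tolerance = 1e-12)
  expect_equal(dbisa(c(-1, 0), 0.5, 4), c(0, 0))
  expect_error(dbisa(1, shape = 0, scale = 4), "positive")
})

test_that("BS survival takes its closed values and decreases in t", {
  expect_equal(sbisa(4, 0.5, 4), 0.5)        # xi(1) = 0
  expect_equal(sbisa(1, 0.5, 4), stats::pnorm(3))  # xi(1/4) = -3/2
  # cross-check against numeric integration of the density
  int <- stats::integrate(function(u) dbisa(u, 0.5, 4), 0, 1,
                          rel.tol = 1e-12)$value
  expect_equal(sbisa(1, 0.5, 4), 1 - int, tolerance = 1e-8)
  expect_equal(sbisa(1e8, 0.5, 4), 0, tolerance = 1e-12)
  t <- seq(0.2, 30, length.out = 100)
  expect_true(all(diff(sbisa(t, 0.5, 4)) < 0))
})

test_that("BS quantile inverts the CDF and its median equals the scale", {
  for (g in c(0.5, 1, 2)) expect_identical(qbisa(0.5, g, 4), 4)
  # independent oracle: invert the integrated density numerically
  q975 <- uniroot(function(t) {
    stats::integrate(function(u) dbisa(u, 0.5, 4), 0, t,
                     rel.tol = 1e-12)$value - 0.975
  }, c(4, 40), tol = 1e-12)$root
  expect_equal(qbisa(0.975, 0.5, 4), q975, tolerance = 1e-8)
  expect_equal(qbisa(0.975, 0.5, 4), 10.29, tolerance = 1e-3)
  p <- seq(0.01, 0.99, length.out = 50)
  expect_equal(pbisa(qbisa(p, 0.8, 2.5), 0.8, 2.5), p, tolerance = 1e-8)
  expect_error(qbisa(1.2, 0.5, 4), "in \\(0, 1\\)")
})

test_that("unconditional generators reproduce analytic moments and laws", {
  withr::with_seed(11, {
    w <- rweibull_ph(1e6, shape = 1, rate = 0.25)
    expect_equal(mean(w), 4, tolerance = 0.02)       # ~5 MC sd
    b <- rbisa(1e6, shape = 0.5, scale = 4)
    expect_equal(median(b), 4, tolerance = 0.02)
    expect_equal(mean(b), 4 * (1 + 0.5^2 / 2), tolerance = 0.02)
    # KS distance against the analytic CDFs
    w5 <- rweibull_ph(1e5, shape = 2, rate = 0.05)
    expect_lt(ks_distance(w5, function(x) pweibull_ph(x, 2, 0.05)), 0.005)
    b5 <- rbisa(1e5, shape = 0.5, scale = 4)
    expect_lt(ks_distance(b5, function(x) pbisa(x, 0.5, 4)), 0.005)
  })
})

test_that("lifetime_model dispatches both families consistently", {
  mw <- lifetime_model("weibull", shape = 2, rate = 0.25)
  mb <- lifetime_model("bs", shape = 0.5, scale = 4)
  expect_equal(model_sf(mw, 2), sweibull_ph(2, 2, 0.25))
  expect_equal(model_pdf(mb, 3), dbisa(3, 0.5, 4))
  expect_equal(model_quantile(mb, 0.5), 4)
  expect_equal(model_mean(mw), 0.25^(-0.5) * gamma(1.5))
  expect_error(lifetime_model("weibull", shape = 2, scale = 4), "rate")
  expect_error(lifetime_model("bs", shape = 2, rate = 4), "scale")
})
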