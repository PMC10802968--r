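# shared fixtures: tiny datasets and fast MCMC settings used across files

toy_mixed <- function() {
  tibble::tibble(time = c(1, 2.5, 0.8, 3), status = c(1, 0, 1, 0))
}

# small but honest sampler settings for unit tests
quick_control <- function(seed = 1, iterations = 3000, burn_in = 300,
                          thin = 3) {
  mcmc_control(iterations = iterations, burn_in = burn_in, thin = thin,
               seed = seed)
}

# degenerate single-point "posterior" fits for closed-form checks
point_fit_weibull <- function(shape, rate, n_draws = 1) {
  new_ba_fit(tibble::tibble(shape = rep(shape, n_draws),
                            scale = rep(rate, n_draws)), "weibull")
}

point_fit_bs <- function(shape, scale, n_draws = 1) {
  new_ba_fit(tibble::tibble(shape = rep(shape, n_draws),
                            scale = rep(scale, n_draws)), "bs")
}

# empirical CDF distance against an analytic CDF
ks_distance <- function(draws, cdf) {
  x <- sort(draws)
  n <- length(x)
  u <- cdf(x)
  max(abs(u - seq_len(n) / n), abs(u - (seq_len(n) - 1) / n))
}
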