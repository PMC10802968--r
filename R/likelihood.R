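#' Censored-data log-likelihood
#'
#' The standard right-censored likelihood: events contribute `log f(t_i)`,
#' censored records contribute `log S(c_i)`.  The second parameter may be a
#' scalar or a per-record vector (for covariate-linked scale regressions
#' `exp(b1 + b2 * x_i)`); for the Weibull family it is the PH rate, for the
#' BS family the scale.
#'
#' @param data data frame with columns `time` (> 0) and `status`
#'   (1 = event, 0 = right-censored).
#' @param family `"weibull"` or `"bs"`.
#' @param shape positive shape parameter.
#' @param scale positive rate/scale, scalar or one value per record.
#' @return Scalar log-likelihood.
#' @examples
#' d <- tibble::tibble(time = c(1, 2), status = c(1, 0))
#' censored_loglik(d, "weibull", shape = 1, scale = 1)  # log f(1) + log S(2)
#' @export
censored_loglik <- function(data, family = c("weibull", "bs"), shape, scale) {
  family <- match.arg(family)
  data <- validate_survival(data, require_covariate = FALSE)
  if (!length(scale) %in% c(1L, nrow(data))) {
    stop("`scale` must be a scalar or one value per record", call. = FALSE)
  }
  check_positive(shape, "shape"); check_positive(scale, "scale")
  scale <- rep_len(scale, nrow(data))
  t <- data$time
  d <- data$status == 1
  ll_terms <- numeric(nrow(data))
  if (family == "weibull") {
    # log f = log(a) + log(b) + (a-1) log t - b t^a ; log S = -b t^a
    ta <- t^shape
    ll_terms[d]  <- log(shape) + log(scale[d]) + (shape - 1) * log(t[d]) -
      scale[d] * ta[d]
    ll_terms[!d] <- -scale[!d] * ta[!d]
  } else {
    z <- (sqrt(t / scale) - sqrt(scale / t)) / shape
    jac <- (t + scale) / (2 * shape * sqrt(scale) * t^1.5)
    ll_terms[d]  <- stats::dnorm(z[d], log = TRUE) + log(jac[d])
    ll_terms[!d] <- stats::pnorm(z[!d], lower.tail = FALSE, log.p = TRUE)
  }
  bad <- which(!is.finite(ll_terms))
  if (length(bad)) {
    stop(sprintf("non-finite log-likelihood contribution at record(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  sum(ll_terms)
}

#' Prior specification for the Bayesian lifetime models
#'
#' Gamma priors (shape, rate hyperparameters) on the positive distribution
#' parameters and independent normal priors on the scale-regression
#' coefficients.  Defaults are the conventional weakly-informative
#' BUGS-style choices: `Gamma(0.01, 0.01)` on shape and scale/rate,
#' `Normal(0, sd = 100)` on `b1` and `b2`.
#'
#' @param shape_prior length-2 gamma (shape, rate) hyperparameters for the
#'   distribution shape.
#' @param scale_prior length-2 gamma (shape, rate) hyperparameters for the
#'   rate/scale (intercept-only models).
#' @param coef_mean,coef_sd normal prior mean and sd for each regression
#'   coefficient.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(shape_prior = c(0.01, 0.01),
                       scale_prior = c(0.01, 0.01),
                       coef_mean = 0, coef_sd = 100) {
  stopifnot(length(shape_prior) == 2, all(shape_prior > 0),
            length(scale_prior) == 2, all(scale_prior > 0),
            is.finite(coef_mean), coef_sd > 0)
  structure(list(shape_prior = shape_prior, scale_prior = scale_prior,
                 coef_mean = coef_mean, coef_sd = coef_sd),
            class = "prior_spec")
}

# fast, non-validating censored log-likelihood used inside the sampler;
# `scale` is scalar or per-record
loglik_fast <- function(family, t, is_event, log_t, shape, scale) {
  if (family == "weibull") {
    scale_v <- rep_len(scale, length(t))
    ll <- sum(is_event) * log(shape) + sum(log(scale_v[is_event])) +
      (shape - 1) * sum(log_t[is_event]) - sum(scale_v * t^shape)
  } else {
    z <- (sqrt(t / scale) - sqrt(scale / t)) / shape
    jac <- (t + scale) / (2 * shape * sqrt(scale) * t^1.5)
    ll <- sum(stats::dnorm(z[is_event], log = TRUE) + log(jac[is_event])) +
      sum(stats::pnorm(z[!is_event], lower.tail = FALSE, log.p = TRUE))
  }
  ll
}

# log posterior density (up to a constant) on the *sampling* scale.
# Parameter vector layout:
#   regression model: (log shape, b1, b2)     [log shape dropped if fixed]
#   intercept-only:   (log shape, log scale)  [idem]
# The log transform of positive parameters carries its Jacobian so the
# chain targets the posterior of the natural parameters.
make_log_post <- function(data, family, priors, covariate, fix_shape = NULL) {
  x <- if (covariate) data$x else NULL
  t <- data$time
  is_event <- data$status == 1
  log_t <- log(t)
  function(par) {
    i <- 1L
    if (is.null(fix_shape)) {
      lshape <- par[i]; i <- i + 1L
      shape <- exp(lshape)
    } else {
      shape <- fix_shape; lshape <- NULL
    }
    if (covariate) {
      b1 <- par[i]; b2 <- par[i + 1L]
      scale <- exp(b1 + b2 * x)
      lp_par <- stats::dnorm(b1, priors$coef_mean, priors$coef_sd, log = TRUE) +
        stats::dnorm(b2, priors$coef_mean, priors$coef_sd, log = TRUE)
    } else {
      lscale <- par[i]
      scale <- exp(lscale)
      lp_par <- stats::dgamma(scale, priors$scale_prior[1],
                              priors$scale_prior[2], log = TRUE) + lscale
    }
    if (!all(is.finite(scale)) || any(scale <= 0) || !is.finite(shape) ||
        shape <= 0) {
      return(-Inf)
    }
    ll <- loglik_fast(family, t, is_event, log_t, shape, scale)
    if (!is.finite(ll)) return(-Inf)
    lp <- ll + lp_par
    if (is.null(fix_shape)) {
      lp <- lp + stats::dgamma(shape, priors$shape_prior[1],
                               priors$shape_prior[2], log = TRUE) + lshape
    }
    lp
  }
}
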