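#' MCMC sampler settings
#'
#' The default protocol runs 1,000 burn-in iterations followed by 100,000
#' sampling iterations thinned by 10, retaining exactly 10,000 draws per
#' parameter.  `iterations` counts post-burn-in iterations; retained draws
#' are `iterations / thin`.
#'
#' @param iterations sampling iterations after burn-in.
#' @param burn_in burn-in iterations (discarded; proposal adaptation happens
#'   only here).
#' @param thin thinning interval.
#' @param seed integer seed; every fit is bitwise reproducible given the
#'   seed and settings.
#' @param adapt adapt the proposal scale during burn-in (Robbins-Monro on
#'   the log step size, targeting ~0.3 acceptance).
#' @param target_accept acceptance rate targeted by the adaptation.
#' @return An object of class `mcmc_control`.
#' @examples
#' mcmc_control()
#' mcmc_control(iterations = 5000, burn_in = 500, thin = 5, seed = 42)
#' @export
mcmc_control <- function(iterations = 100000, burn_in = 1000, thin = 10,
                         seed = 1L, adapt = TRUE, target_accept = 0.3) {
  stopifnot(iterations >= 1, burn_in >= 0, thin >= 1,
            iterations %% thin == 0, target_accept > 0, target_accept < 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), adapt = isTRUE(adapt),
                 target_accept = target_accept),
            class = "mcmc_control")
}

#' Fit a Bayesian lifetime model to right-censored data
#'
#' Samples the posterior of a Weibull (PH rate) or Birnbaum-Saunders model
#' under the censored-data likelihood and the priors in [prior_spec()],
#' using an adaptive random-walk Metropolis sampler on log-transformed
#' positive parameters (regression coefficients untransformed).  If the
#' data carry a binary covariate column `x` the rate/scale is modelled as
#' `exp(b1 + b2 * x)` and the sampled parameters are `(shape, b1, b2)`;
#' otherwise `(shape, scale)`.
#'
#' The proposal is a joint multivariate normal whose covariance is the
#' inverse curvature of the log posterior at its mode (found with
#' [stats::optim()]), scaled by `2.38^2 / d`; during burn-in only, the
#' global step size adapts towards the target acceptance rate and is then
#' frozen, so the post-burn-in chain is a valid time-homogeneous Metropolis
#' chain.
#'
#' @param data data frame with columns `time`, `status` and optionally a
#'   binary `x`.
#' @param family `"weibull"` or `"bs"`.
#' @param priors a [prior_spec()].
#' @param control an [mcmc_control()].
#' @param use_covariate `"auto"` (use `x` when present), `TRUE` or `FALSE`.
#' @param fix_shape optional positive value at which the shape parameter is
#'   held fixed (e.g. `1` for the exponential sub-model of the Weibull).
#' @return An object of class `ba_fit` with elements `draws` (a tibble of
#'   retained posterior draws on the natural scale), `family`, `data`,
#'   `acceptance`, `control`, `priors`, `covariate`.  Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   `autoplot()`.
#' @examples
#' d <- simulate_scenario("weibull", shape = 1, n = 60, theta = 0.08,
#'                        b1 = -1.5, b2 = 0.4, seed = 1)
#' fit <- fit_survival_bayes(d, "weibull",
#'                           control = mcmc_control(2000, 200, 2, seed = 1))
#' tidy(fit)
#' @export
fit_survival_bayes <- function(data, family = c("weibull", "bs"),
                               priors = prior_spec(),
                               control = mcmc_control(),
                               use_covariate = "auto",
                               fix_shape = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(priors, "prior_spec"), inherits(control, "mcmc_control"))
  covariate <- resolve_covariate(data, use_covariate)
  data <- validate_survival(data, require_covariate = covariate)
  if (!is.null(fix_shape)) check_positive(fix_shape, "fix_shape")

  par_names <- c(if (is.null(fix_shape)) "shape",
                 if (covariate) c("b1", "b2") else "scale")
  log_post <- make_log_post(data, family, priors, covariate, fix_shape)

  res <- with_seed_if(control$seed, {
    init <- mcmc_init(log_post, data, family, covariate, fix_shape)
    run_metropolis(log_post, init, control)
  })

  draws <- res$draws
  # back-transform to the natural scale
  natural <- draws
  j <- 1L
  if (is.null(fix_shape)) { natural[, j] <- exp(draws[, j]); j <- j + 1L }
  if (!covariate) natural[, ncol(natural)] <- exp(draws[, ncol(draws)])
  colnames(natural) <- par_names
  out <- list(draws = tibble::as_tibble(as.data.frame(natural)),
              family = family, data = data, covariate = covariate,
              acceptance = res$acceptance, control = control,
              priors = priors, fix_shape = fix_shape,
              step_scale = res$step_scale)
  class(out) <- "ba_fit"
  if (res$acceptance < 0.05 || res$acceptance > 0.95) {
    warning(sprintf("post-adaptation acceptance rate %.3f is outside [0.05, 0.95]",
                    res$acceptance), call. = FALSE)
  }
  out
}

#' @rdname fit_survival_bayes
#' @export
fit_scale_regression <- function(data, family = c("weibull", "bs"),
                                 priors = prior_spec(),
                                 control = mcmc_control(),
                                 fix_shape = NULL) {
  if (!"x" %in% names(data)) {
    stop("scale regression needs a binary covariate column `x`", call. = FALSE)
  }
  fit_survival_bayes(data, family, priors, control,
                     use_covariate = TRUE, fix_shape = fix_shape)
}

resolve_covariate <- function(data, use_covariate) {
  if (identical(use_covariate, "auto")) return("x" %in% names(data))
  isTRUE(use_covariate)
}

# crude moment-based start, refined by a mode search; returns the start
# vector and a proposal covariance from the curvature at the mode
mcmc_init <- function(log_post, data, family, covariate, fix_shape) {
  ev <- data$time[data$status == 1]
  if (!length(ev)) ev <- data$time
  m <- mean(ev)
  start <- c(if (is.null(fix_shape)) 0,                       # log shape = 0
             if (covariate) c(log_start_scale(family, m), 0)
             else log(start_scale(family, m)))
  d <- length(start)
  opt <- tryCatch(
    stats::optim(start, function(p) -log_post(p), method = "BFGS",
                 hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value)) {
    start <- opt$par
    cov <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(cov) && all(is.finite(cov)) &&
        all(eigen(cov, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      return(list(par = start, cov = cov))
    }
  }
  list(par = start, cov = diag(0.01, d))
}

start_scale <- function(family, mean_time) {
  # shape-1 moment match: weibull rate 1/mean, bs scale ~ mean
  if (family == "weibull") 1 / mean_time else mean_time
}

log_start_scale <- function(family, mean_time) log(start_scale(family, mean_time))

# adaptive random-walk Metropolis; adaptation of the global log step size
# by Robbins-Monro during burn-in only
run_metropolis <- function(log_post, init, control) {
  d <- length(init$par)
  chol_cov <- chol(init$cov)
  log_step <- log(2.38 / sqrt(d))
  cur <- init$par
  cur_lp <- log_post(cur)
  if (!is.finite(cur_lp)) {
    # fall back to a wide prior-ish start
    cur <- rep(0, d)
    cur_lp <- log_post(cur)
    if (!is.finite(cur_lp)) stop("could not find a starting value with ",
                                 "finite posterior density", call. = FALSE)
  }
  n_total <- control$burn_in + control$iterations
  keep <- control$iterations %/% control$thin
  draws <- matrix(NA_real_, nrow = keep, ncol = d)
  acc_post <- 0L; n_post <- 0L
  k <- 0L
  for (i in seq_len(n_total)) {
    prop <- cur + exp(log_step) * drop(stats::rnorm(d) %*% chol_cov)
    prop_lp <- log_post(prop)
    accepted <- is.finite(prop_lp) &&
      (prop_lp - cur_lp >= 0 || log(stats::runif(1)) < prop_lp - cur_lp)
    if (accepted) { cur <- prop; cur_lp <- prop_lp }
    if (i <= control$burn_in) {
      if (control$adapt) {
        log_step <- log_step +
          (as.numeric(accepted) - control$target_accept) / sqrt(i)
      }
    } else {
      n_post <- n_post + 1L
      acc_post <- acc_post + as.integer(accepted)
      if (n_post %% control$thin == 0L) {
        k <- k + 1L
        draws[k, ] <- cur
      }
    }
  }
  if (n_post > 0L && acc_post == 0L) {
    stop("the sampler rejected every proposal after burn-in", call. = FALSE)
  }
  list(draws = draws, acceptance = acc_post / max(n_post, 1L),
       step_scale = exp(log_step))
}

#' Assemble a posterior-draws object by hand
#'
#' Low-level constructor used when the posterior draws come from somewhere
#' other than [fit_survival_bayes()] — e.g. a degenerate single-point
#' "posterior" for validating the imputation layer against closed forms.
#'
#' @param draws data frame of posterior draws on the natural scale; columns
#'   `shape` plus either `scale` or `b1`,`b2`.
#' @param family `"weibull"` or `"bs"`.
#' @param data the dataset the draws refer to (optional for pure prediction).
#' @return A `ba_fit` object.
#' @examples
#' fit <- new_ba_fit(tibble::tibble(shape = 2, scale = 0.25), "weibull")
#' @export
new_ba_fit <- function(draws, family = c("weibull", "bs"), data = NULL) {
  family <- match.arg(family)
  draws <- tibble::as_tibble(draws)
  covariate <- all(c("b1", "b2") %in% names(draws))
  if (!covariate && !"scale" %in% names(draws)) {
    stop("`draws` needs either a `scale` column or `b1` and `b2`",
         call. = FALSE)
  }
  structure(list(draws = draws, family = family, data = data,
                 covariate = covariate, acceptance = NA_real_,
                 control = NULL, priors = NULL, fix_shape = NULL),
            class = "ba_fit")
}

#' @export
print.ba_fit <- function(x, ...) {
  cat(sprintf("<ba_fit> %s model, %d retained draws (%s)\n",
              x$family, nrow(x$draws),
              if (x$covariate) "scale regression on x" else "intercept only"))
  if (is.finite(x$acceptance)) {
    cat(sprintf("  acceptance rate %.3f\n", x$acceptance))
  }
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a fitted lifetime model
#'
#' @param x a `ba_fit`.
#' @param conf_level posterior interval level.
#' @param ... unused.
#' @return A tibble with one row per parameter: posterior mean, median, sd
#'   and equal-tailed interval bounds.
#' @method tidy ba_fit
#' @export
tidy.ba_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  x$draws |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      estimate  = mean(.data$value),
      median    = stats::median(.data$value),
      std.error = stats::sd(.data$value),
      conf.low  = stats::quantile(.data$value, a, names = FALSE),
      conf.high = stats::quantile(.data$value, 1 - a, names = FALSE),
      .groups = "drop") |>
    dplyr::arrange(match(.data$term, c("shape", "scale", "b1", "b2")))
}

#' One-row model-level summary of a fitted lifetime model
#'
#' @param x a `ba_fit` fitted to data.
#' @param ... unused.
#' @return A tibble with the family, data dimensions, retained draw count,
#'   acceptance rate and DIC decomposition.
#' @method glance ba_fit
#' @export
glance.ba_fit <- function(x, ...) {
  if (is.null(x$data)) {
    stop("glance() needs a fit that carries its data", call. = FALSE)
  }
  d <- dic(x)
  tibble::tibble(family = x$family, n = nrow(x$data),
                 n_event = sum(x$data$status == 1),
                 n_censored = sum(x$data$status == 0),
                 retained = nrow(x$draws), acceptance = x$acceptance,
                 mean_deviance = d$mean_deviance, p_d = d$p_d, dic = d$dic)
}

# per-record scale (rate for weibull, scale for bs) for one posterior draw
draw_scale <- function(fit, draw, x = NULL) {
  if (fit$covariate) {
    if (is.null(x)) stop("this fit has a covariate; supply `x`", call. = FALSE)
    exp(draw[["b1"]] + draw[["b2"]] * x)
  } else {
    draw[["scale"]]
  }
}

fit_shape <- function(fit, draw) {
  if ("shape" %in% names(draw)) draw[["shape"]] else fit$fix_shape
}
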