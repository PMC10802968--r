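#' Event-time model with a binary-covariate scale mixture
#'
#' The simulation design generates the Weibull PH rate or the BS scale
#' through a log-linear regression on a Bernoulli(`covariate_prob`)
#' covariate, `scale = exp(b1 + b2 * x)`.  This object captures one such
#' generating model; the calibration functions integrate over the covariate
#' analytically (a two-component mixture).
#'
#' @param family `"weibull"` or `"bs"`.
#' @param shape positive shape parameter.
#' @param b1,b2 regression coefficients on the log scale/rate.
#' @param covariate_prob probability that the covariate equals 1 (default
#'   0.5, the balanced design used throughout the simulation study).
#' @return An object of class `event_mixture`.
#' @examples
#' event_mixture("weibull", shape = 1, b1 = -1.5, b2 = 0.4)
#' @export
event_mixture <- function(family = c("weibull", "bs"), shape, b1, b2,
                          covariate_prob = 0.5) {
  family <- match.arg(family)
  check_positive(shape, "shape")
  stopifnot(is.finite(b1), is.finite(b2),
            covariate_prob >= 0, covariate_prob <= 1)
  structure(list(family = family, shape = shape, b1 = b1, b2 = b2,
                 covariate_prob = covariate_prob),
            class = "event_mixture")
}

mixture_components <- function(model) {
  par2 <- exp(model$b1 + model$b2 * c(0, 1))
  w <- c(1 - model$covariate_prob, model$covariate_prob)
  list(
    models = lapply(par2, function(s) {
      if (model$family == "weibull") {
        lifetime_model("weibull", model$shape, rate = s)
      } else {
        lifetime_model("bs", model$shape, scale = s)
      }
    }),
    weights = w
  )
}

mixture_sf <- function(model, t) {
  cmp <- mixture_components(model)
  cmp$weights[1] * model_sf(cmp$models[[1]], t) +
    cmp$weights[2] * model_sf(cmp$models[[2]], t)
}

#' Expected censoring fraction under exponential censoring
#'
#' With event times `T` drawn from an `event_mixture` and independent
#' censoring times `C ~ Exponential(rate = theta)` (the MAR mechanism of
#' the simulation design), the expected fraction of censored records is
#' \deqn{P(C < T) = E_x\!\left[\int_0^\infty \theta e^{-\theta c}
#'       \, S_T(c \mid x) \, dc\right],}
#' computed by adaptive quadrature (closed form `theta / (theta + rate)`
#' per mixture component when the event law is exponential).  The fraction
#' is strictly increasing in `theta`, which [calibrate_theta()] exploits.
#'
#' @param theta positive exponential censoring rate.
#' @param model an [event_mixture()].
#' @return Scalar censoring probability in (0, 1).
#' @examples
#' m <- event_mixture("weibull", 1, b1 = log(0.25), b2 = 0)
#' expected_censoring_fraction(0.25, m)  # 0.5: competing exponentials
#' @export
expected_censoring_fraction <- function(theta, model) {
  check_positive(theta, "theta")
  stopifnot(inherits(model, "event_mixture"))
  cmp <- mixture_components(model)
  vals <- vapply(cmp$models, function(m) {
    if (m$family == "weibull" && m$shape == 1) {
      return(theta / (theta + m$par2))   # competing exponentials
    }
    # substitute u = exp(-theta c): P(C < T) = int_0^1 S_T(-log(u)/theta) du,
    # a bounded smooth integrand for any theta
    int <- stats::integrate(function(u) {
      model_sf(m, pmax(-log(u) / theta, .Machine$double.xmin))
    }, 0, 1, rel.tol = 1e-10)
    if (int$message != "OK") {
      stop("quadrature for the censoring fraction failed: ", int$message,
           call. = FALSE)
    }
    int$value
  }, numeric(1))
  sum(cmp$weights * vals)
}

#' Calibrate the exponential censoring rate to a nominal censoring fraction
#'
#' Finds the rate `theta` such that the expected censoring fraction
#' [expected_censoring_fraction()] equals `target_p`, by bracketing root
#' search on log(theta).  This is the analytic counterpart of the working
#' rate tables used by the simulation grid (see [theta_table()]); the two
#' do not agree exactly because the tabulated values are rounded to two
#' decimals, and both are exposed.
#'
#' @param target_p nominal censoring fraction in (0, 1).
#' @param model an [event_mixture()].
#' @param tol absolute tolerance on the achieved fraction.
#' @return Positive scalar rate.
#' @examples
#' m <- event_mixture("weibull", 1, b1 = log(0.25), b2 = 0)
#' calibrate_theta(0.5, m)  # 0.25
#' @export
calibrate_theta <- function(target_p, model, tol = 1e-10) {
  stopifnot(target_p > 0, target_p < 1, inherits(model, "event_mixture"))
  f <- function(lt) expected_censoring_fraction(exp(lt), model) - target_p
  lo <- -10; hi <- 10
  for (i in 1:50) {
    if (f(lo) < 0) break
    lo <- lo - 5
  }
  for (i in 1:50) {
    if (f(hi) > 0) break
    hi <- hi + 5
  }
  if (f(lo) >= 0 || f(hi) <= 0) {
    stop("could not bracket the calibration root", call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)
  theta <- exp(root$root)
  if (abs(expected_censoring_fraction(theta, model) - target_p) > max(tol, 1e-8)) {
    stop("calibration root did not converge to the target fraction",
         call. = FALSE)
  }
  theta
}

#' Working parameter tables for the simulation grid
#'
#' `theta_table()` returns the bundled exponential censoring rates used by
#' the simulation study for each (shape, nominal censoring) cell —
#' two-decimal working values, not exact solutions of the calibration
#' equation.  For the BS family the published rates vary slightly with the
#' sample size; `n` selects the column.  `coef_table()` returns the scale
#' regression coefficients `(b1, b2)` per shape, chosen so that the average
#' scale is close to 4 time units.
#'
#' @param family `"weibull"` or `"bs"`.
#' @param n sample size column for the BS rates (100, 200 or 300).
#' @return A tibble with columns `shape`, `nominal_p`, `theta`
#'   (`theta_table`) or `shape`, `b1`, `b2` (`coef_table`).
#' @examples
#' theta_table("weibull")
#' coef_table("bs")
#' @export
theta_table <- function(family = c("weibull", "bs"), n = 200) {
  family <- match.arg(family)
  if (family == "weibull") {
    tibble::tibble(
      shape     = rep(c(0.5, 1, 2), each = 3),
      nominal_p = rep(c(0.10, 0.20, 0.50), times = 3),
      theta     = c(0.02, 0.04, 0.30,
                    0.04, 0.08, 0.30,
                    0.02, 0.06, 0.20))
  } else {
    stopifnot(n %in% c(100, 200, 300))
    col <- match(n, c(100, 200, 300))
    th <- list(
      `10` = matrix(c(0.01, 0.02, 0.03,
                      0.02, 0.01, 0.02,
                      0.01, 0.01, 0.01), nrow = 3, byrow = TRUE),
      `20` = matrix(c(0.04, 0.04, 0.05,
                      0.04, 0.04, 0.04,
                      0.02, 0.02, 0.02), nrow = 3, byrow = TRUE),
      `50` = matrix(c(0.15, 0.15, 0.15,
                      0.15, 0.15, 0.15,
                      0.10, 0.15, 0.15), nrow = 3, byrow = TRUE))
    tibble::tibble(
      shape     = rep(c(0.5, 1, 2), each = 3),
      nominal_p = rep(c(0.10, 0.20, 0.50), times = 3),
      theta     = as.vector(t(cbind(th$`10`[, col], th$`20`[, col],
                                    th$`50`[, col]))))
  }
}

#' @rdname theta_table
#' @export
coef_table <- function(family = c("weibull", "bs")) {
  family <- match.arg(family)
  if (family == "weibull") {
    tibble::tibble(shape = c(0.5, 1, 2),
                   b1 = c(-0.80, -1.5, -3),
                   b2 = c(0.20, 0.40, 0.3))
  } else {
    tibble::tibble(shape = c(0.5, 1, 2),
                   b1 = rep(1.37, 3),
                   b2 = rep(0.15, 3))
  }
}
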