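#' Kaplan-Meier product-limit estimator
#'
#' The classic nonparametric survival curve: at each distinct event time
#' `t_(j)` the curve drops by the factor `1 - d_j / r_j` (events over
#' at-risk).  Ties follow the standard convention that records censored at
#' an event time are still at risk for that event.  An all-censored
#' dataset yields a curve constant at 1, with a warning.
#'
#' @param data survival data frame with `time` and `status`.
#' @return A tibble of class `ba_km` with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `n_censor` (censorings in `[t_j,
#'   t_{j+1})`), `survival`.
#' @examples
#' km_curve(tibble::tibble(time = 1:4, status = 1))
#' @export
km_curve <- function(data) {
  data <- validate_survival(data)
  if (!any(data$status == 1)) {
    warning("no events: the product-limit curve is constant at 1",
            call. = FALSE)
    out <- tibble::tibble(time = numeric(), n_risk = integer(),
                          n_event = integer(), n_censor = integer(),
                          survival = numeric())
    return(tibble::new_tibble(out, class = "ba_km"))
  }
  ord <- order(data$time, -data$status)  # events before censorings at ties
  t_sorted <- data$time[ord]
  s_sorted <- data$status[ord]
  ev_times <- sort(unique(t_sorted[s_sorted == 1]))
  n <- length(t_sorted)
  rows <- purrr::map_dfr(ev_times, function(tj) {
    tibble::tibble(time = tj,
                   n_risk = sum(t_sorted >= tj),
                   n_event = sum(t_sorted == tj & s_sorted == 1))
  })
  rows$survival <- cumprod(1 - rows$n_event / rows$n_risk)
  # censorings falling in [t_j, t_{j+1})
  cens_t <- t_sorted[s_sorted == 0]
  rows$n_censor <- vapply(seq_along(ev_times), function(j) {
    upper <- if (j < length(ev_times)) ev_times[j + 1] else Inf
    sum(cens_t >= ev_times[j] & cens_t < upper)
  }, integer(1))
  rows <- rows[, c("time", "n_risk", "n_event", "n_censor", "survival")]
  tibble::new_tibble(rows, class = "ba_km")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation; 1 before the first event.
#'
#' @param km a `ba_km` curve.
#' @param t times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "ba_km"))
  if (!nrow(km)) return(rep(1, length(t)))
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Comparison curve set: original, omit-censored and imputation-augmented
#'
#' Builds the three survival curves used to judge the imputation visually:
#' (a) the Kaplan-Meier curve of the original censored data, (b) the curve
#' of the events only ("omitting censored"), and (c) the curve of the
#' augmented data with every imputed time treated as an exact event (the
#' Bayesian-augmentation curve — a complete-data step function reaching
#' zero).  The per-censor draw bands come along as an attribute for
#' plotting the spread of the predictive draws.
#'
#' @param data the original survival data frame.
#' @param imputation a `ba_imputation` derived from `data`.
#' @return A tibble of class `ba_curveset` with columns `curve`
#'   (`"km"`, `"omit_censored"`, `"ba_imputed"`), `time`, `survival`,
#'   `n_risk`, `n_event`; attribute `band` holds [draw_band()] output.
#' @examples
#' d <- simulate_scenario("weibull", 1, n = 50, theta = 0.15,
#'                        b1 = -1.5, b2 = 0.4, seed = 5)
#' fit <- new_ba_fit(tibble::tibble(shape = 1, b1 = -1.5, b2 = 0.4), "weibull")
#' imp <- impute_censored(d, fit, seed = 6)
#' curve_set(d, imp)
#' @export
curve_set <- function(data, imputation) {
  stopifnot(inherits(imputation, "ba_imputation"))
  data <- validate_survival(data)
  if (nrow(imputation$summaries) &&
      !all(imputation$summaries$time %in% data$time)) {
    stop("`imputation` does not look like it was derived from `data`",
         call. = FALSE)
  }
  events_only <- dplyr::filter(data, .data$status == 1)
  aug <- augmented_data(imputation) |>
    dplyr::mutate(time = .data$imputed_time, status = 1)
  pieces <- list(
    km            = km_curve(data),
    omit_censored = km_curve(events_only),
    ba_imputed    = km_curve(aug))
  out <- purrr::imap_dfr(pieces, function(cv, nm) {
    dplyr::mutate(tibble::as_tibble(cv), curve = nm, .before = 1)
  })
  out <- tibble::new_tibble(out, class = "ba_curveset")
  attr(out, "band") <- draw_band(imputation)
  out
}
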