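#' Plot a Kaplan-Meier curve
#'
#' @param object a `ba_km` curve.
#' @param ... unused.
#' @return A ggplot object (step curve).
#' @method autoplot ba_km
#' @export
autoplot.ba_km <- function(object, ...) {
  df <- km_step_frame(tibble::as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Plot the original / omit-censored / imputation-augmented curve trio
#'
#' One step curve per comparison curve, optionally overlaid with the
#' per-censor predictive draw bands (95% band as vertical segments at each
#' censoring time).
#'
#' @param object a `ba_curveset`.
#' @param band overlay the per-censor draw bands.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ba_curveset
#' @export
autoplot.ba_curveset <- function(object, band = FALSE, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$curve) |>
    dplyr::group_modify(~ km_step_frame(.x)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                        colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = NULL) +
    ggplot2::theme_minimal()
  bd <- attr(object, "band")
  if (band && !is.null(bd) && nrow(bd)) {
    p <- p + ggplot2::geom_segment(
      data = bd, inherit.aes = FALSE, alpha = 0.4,
      ggplot2::aes(x = .data$time, xend = .data$q97.5,
                   y = km_survival_at_curve(object, .data$time),
                   yend = km_survival_at_curve(object, .data$time)))
  }
  p
}

# prepend the (0, 1) anchor so the step starts at full survival
km_step_frame <- function(df) {
  if (!nrow(df)) return(tibble::tibble(time = 0, survival = 1))
  dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                   df[c("time", "survival")])
}

km_survival_at_curve <- function(object, t) {
  km <- tibble::as_tibble(object) |> dplyr::filter(.data$curve == "km")
  if (!nrow(km)) return(rep(1, length(t)))
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Trace, posterior-density and autocorrelation panels for a fit
#'
#' @param object a `ba_fit`.
#' @param type `"trace"`, `"density"` or `"acf"`.
#' @param ... unused.
#' @return A ggplot object faceted by parameter.
#' @method autoplot ba_fit
#' @export
autoplot.ba_fit <- function(object, type = c("trace", "density", "acf"), ...) {
  type <- match.arg(type)
  long <- object$draws |>
    dplyr::mutate(.draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-".draw", names_to = "term")
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.draw, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "retained draw", y = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "density") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density") +
      ggplot2::theme_minimal()
  } else {
    acfs <- purrr::map_dfr(names(object$draws), function(p) {
      dplyr::mutate(chain_acf(object$draws[[p]],
                              max_lag = min(40L, nrow(object$draws) - 1L)),
                    term = p)
    })
    ggplot2::ggplot(acfs, ggplot2::aes(x = .data$lag, y = .data$acf)) +
      ggplot2::geom_col(width = 0.2) +
      ggplot2::facet_wrap(~term) +
      ggplot2::theme_minimal()
  }
}
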