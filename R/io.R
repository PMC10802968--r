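#' Read and validate a right-censored survival dataset
#'
#' Reads a delimited file with header columns `time`, `status` and
#' optionally `x`, and validates it: times strictly positive, `status` in
#' \{0, 1\} (1 = event, 0 = right-censored), `x` in \{0, 1\} when present.
#' Malformed rows are reported by row number.
#'
#' @param path path to a CSV file.
#' @return A validated tibble with columns `time`, `status` and optionally
#'   `x`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(time = c(3, 5), status = c(1, 0)), f)
#' read_survival(f)
#' @export
read_survival <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_survival(raw)
}

#' @rdname read_survival
#' @param data a survival data frame to write.
#' @export
write_survival <- function(data, path) {
  readr::write_csv(validate_survival(data), path)
  invisible(path)
}

validate_survival <- function(data, require_covariate = FALSE) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("survival data must be a nonempty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(c("time", "status"), names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_time <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad_time)) {
    stop("non-positive or missing `time` at row(s) ",
         paste(utils::head(bad_time, 5), collapse = ", "), call. = FALSE)
  }
  bad_status <- which(!data$status %in% c(0, 1))
  if (length(bad_status)) {
    stop("`status` must be 0 (censored) or 1 (event); offending row(s) ",
         paste(utils::head(bad_status, 5), collapse = ", "), call. = FALSE)
  }
  if ("x" %in% names(data)) {
    bad_x <- which(!data$x %in% c(0, 1))
    if (length(bad_x)) {
      stop("covariate `x` must be binary 0/1; offending row(s) ",
           paste(utils::head(bad_x, 5), collapse = ", "), call. = FALSE)
    }
  } else if (require_covariate) {
    stop("a binary covariate column `x` is required here", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Write curve sets, chains and diagnostics to disk
#'
#' Plain-text exports used by the command-line interface: Kaplan-Meier
#' style step curves as TSV, posterior chains as CSV, and a diagnostics
#' report as JSON.
#'
#' @param x object to write (a `ba_curveset`, `ba_fit` or `ba_diagnostics`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @name io_write
NULL

#' @rdname io_write
#' @export
write_curves <- function(x, path) {
  stopifnot(inherits(x, "ba_curveset"))
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname io_write
#' @export
write_chains <- function(x, path) {
  stopifnot(inherits(x, "ba_fit"))
  readr::write_csv(x$draws, path)
  invisible(path)
}

#' @rdname io_write
#' @export
write_diagnostics <- function(x, path) {
  stopifnot(inherits(x, "ba_diagnostics"))
  payload <- list(
    parameters = tibble::as_tibble(x),
    dic = attr(x, "dic"),
    acceptance = attr(x, "acceptance"),
    thresholds = attr(x, "thresholds"),
    pass = attr(x, "pass"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
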