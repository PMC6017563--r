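#' Concentration-time series
#'
#' A time-ordered analyte concentration profile for one subject or a group
#' mean: strictly increasing times in hours, non-negative concentrations in
#' ng/mL.
#'
#' @param times Sampling times (h), strictly increasing, `>= 0`.
#' @param values Concentrations (ng/mL), same length, `>= 0` (tiny negative
#'   round-off below 1e-12 is zeroed).
#' @param analyte `"leuprolide"` or `"testosterone"`.
#' @param meta Optional named list of labels (subject, group, ...).
#' @return A `conc_series` object.
#' @export
conc_series <- function(times, values,
                        analyte = c("leuprolide", "testosterone"),
                        meta = list()) {
  analyte <- match.arg(analyte)
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1L)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  values[values < 0 & values > -1e-12] <- 0
  if (any(values < 0)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 analyte = analyte, meta = meta),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> %s, %d points, t = %g..%g h, C = %.4g..%.4g ng/mL\n",
              x$analyte, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.conc_series <- function(x, ...) {
  data.frame(analyte = x$analyte, time_h = x$times, conc_ng_ml = x$values)
}

# Linear interpolant of a conc_series, constant-extrapolated at the edges.
conc_interpolant <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  stats::approxfun(series$times, series$values, method = "linear", rule = 2)
}
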