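#' Construct an MRI signal-intensity time series
#'
#' A `signal_series` holds ROI-averaged T1-weighted signal intensities for a
#' single compartment (cerebral artery or brain tissue) on a common time grid.
#' Times are in minutes with `t = 0` at the first post-contrast frame, so
#' pre-contrast frames carry negative times; rate constants estimated
#' downstream are therefore in 1/min.
#'
#' @param times Numeric vector of acquisition times in minutes, strictly
#'   increasing, length >= 3.
#' @param values Numeric vector of signal intensities (arbitrary units), same
#'   length as `times`.
#' @param compartment `"artery"` or `"tissue"`.
#' @return An object of class `signal_series`: a data frame with columns
#'   `time` and `value` plus a `compartment` attribute.
#' @seealso [concentration_series()], [signal_to_concentration()]
#' @export
signal_series <- function(times, values, compartment = c("tissue", "artery")) {
  compartment <- match.arg(compartment)
  validate_series(times, values)
  structure(
    data.frame(time = as.numeric(times), value = as.numeric(values)),
    compartment = compartment,
    class = c("signal_series", "data.frame")
  )
}

#' Construct a contrast-agent concentration time series
#'
#' Gadolinium concentration (mM) for one compartment on a common time grid in
#' minutes. Pre-contrast frames (negative times) are zero by construction.
#'
#' @inheritParams signal_series
#' @param values Numeric vector of concentrations in mM, finite.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(times, values,
                                 compartment = c("tissue", "artery")) {
  compartment <- match.arg(compartment)
  validate_series(times, values)
  if (!all(is.finite(values))) {
    stop("concentration values must be finite", call. = FALSE)
  }
  structure(
    data.frame(time = as.numeric(times), value = as.numeric(values)),
    compartment = compartment,
    class = c("concentration_series", "data.frame")
  )
}

validate_series <- function(times, values) {
  if (length(times) != length(values)) {
    stop("times and values must have the same length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("a series needs at least 3 samples", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("times and values must not contain missing values", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (violated at sample %d)",
                 bad), call. = FALSE)
  }
  invisible(TRUE)
}

series_compartment <- function(x) attr(x, "compartment", exact = TRUE)

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("<signal_series: %s, %d frames, t = [%.2f, %.2f] min>\n",
              series_compartment(x), nrow(x), min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more frames\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series: %s, %d frames, t = [%.2f, %.2f] min>\n",
              series_compartment(x), nrow(x), min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more frames\n", nrow(x) - 6L))
  invisible(x)
}

# Post-contrast subset (t >= 0); keeps class and compartment.
post_contrast <- function(x) {
  keep <- x$time >= 0
  structure(
    data.frame(time = x$time[keep], value = x$value[keep]),
    compartment = series_compartment(x),
    class = class(x)
  )
}
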