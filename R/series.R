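#' Construct a sensor stream
#'
#' One raw sample sequence from one platform/parameter combination:
#' timestamped values in the parameter's native unit (HR in bpm, IBI in ms,
#' ECG in mV, GSR in microsiemens). Timestamps are milliseconds since
#' session start and must be strictly increasing.
#'
#' @param participant_id Participant label, e.g. `"RP 1-5"`.
#' @param platform One of VP, BH, E4.
#' @param parameter One of HR, IBI, ECG, GSR.
#' @param t Numeric vector of timestamps (ms), strictly increasing.
#' @param v Numeric vector of values, finite, same length as `t`.
#' @param nominal_rate Sampling rate in Hz; inferred from the median sample
#'   spacing when `NULL`.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(participant_id, platform, parameter, t, v,
                          nominal_rate = NULL) {
  platform <- match.arg(platform, .PLATFORMS)
  parameter <- match.arg(parameter, c("HR", "IBI", "ECG", "GSR"))
  cap <- platform_capabilities()
  if (!any(cap$platform == platform & cap$parameter == parameter))
    stop("platform '", platform, "' does not measure '", parameter, "'",
         call. = FALSE)
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v)) stop("t and v lengths differ", call. = FALSE)
  if (length(t) == 0L) stop("empty stream", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(v)))
    stop("non-finite sample in stream", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timestamps not strictly increasing", call. = FALSE)
  if (is.null(nominal_rate)) {
    nominal_rate <- if (length(t) > 1L) 1000 / stats::median(diff(t)) else NA_real_
  }
  if (!is.na(nominal_rate) && nominal_rate <= 0)
    stop("nominal_rate must be positive", call. = FALSE)
  structure(
    list(participant_id = participant_id, platform = platform,
         parameter = parameter, nominal_rate = nominal_rate, t = t, v = v),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s %s %s: %d samples @ %.3g Hz, %.1f-%.1f s\n",
              x$participant_id, x$platform, x$parameter, length(x$t),
              x$nominal_rate, min(x$t) / 1000, max(x$t) / 1000))
  invisible(x)
}

#' Construct a parameter series
#'
#' One named channel on a regular time grid, the working unit of the
#' benchmark battery. `scale` records whether values are in the parameter's
#' original unit or rescaled to the unit interval; `provenance` accumulates
#' the names of transforms applied, in order.
#'
#' @param name A [channel_name()] object (or a string parsed by
#'   [parse_channel()]).
#' @param t Regular grid of timestamps (ms).
#' @param v Values; `NA` marks missing cells prior to interpolation.
#' @param scale `"original"` or `"rescaled01"`.
#' @param provenance Character vector of applied transforms.
#' @return An object of class `parameter_series`.
#' @export
parameter_series <- function(name, t, v, scale = c("original", "rescaled01"),
                             provenance = character()) {
  if (is.character(name)) name <- parse_channel(name)
  stopifnot(inherits(name, "channel_name"))
  scale <- match.arg(scale)
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v)) stop("t and v lengths differ", call. = FALSE)
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("grid not increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("grid not regular", call. = FALSE)
  }
  structure(
    list(name = name, t = t, v = v, scale = scale, provenance = provenance),
    class = "parameter_series"
  )
}

#' @export
print.parameter_series <- function(x, ...) {
  cat(sprintf("<parameter_series> %s: n=%d, res=%.4g ms, scale=%s, missing=%d\n",
              format(x$name), length(x$t), series_resolution(x), x$scale,
              sum(is.na(x$v))))
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
length.parameter_series <- function(x) length(x$t)

#' Grid step of a parameter series in milliseconds
#' @param s A `parameter_series`.
#' @return Numeric scalar (ms); `NA` for a single-point series.
#' @export
series_resolution <- function(s) {
  if (length(s$t) < 2L) return(NA_real_)
  stats::median(diff(s$t))
}

#' Sampling rate of a parameter series in Hz
#' @param s A `parameter_series`.
#' @return Numeric scalar (Hz).
#' @export
series_rate <- function(s) 1000 / series_resolution(s)

with_provenance <- function(s, tag) {
  s$provenance <- c(s$provenance, tag)
  s
}

stopifnot_gapfree <- function(s, what) {
  if (anyNA(s$v))
    stop(what, " requires a gap-free series; run spline_fill() first",
         call. = FALSE)
}
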