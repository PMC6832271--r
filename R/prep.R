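#' Fill interior gaps with a natural cubic spline
#'
#' Missing cells introduced by the grid alignment are filled by a natural
#' cubic spline through the observed samples, which uses data on both sides
#' of a gap and keeps oscillation low. Observed values are left untouched.
#' Leading and trailing missing cells cannot be interpolated and are
#' trimmed, so the result covers exactly the observed span.
#'
#' @param s A [parameter_series()] with at least 4 observed points.
#' @return A gap-free `parameter_series`.
#' @export
spline_fill <- function(s) {
  stopifnot(inherits(s, "parameter_series"))
  obs <- which(!is.na(s$v))
  if (length(obs) == 0L) stop("all-missing channel", call. = FALSE)
  if (length(obs) < 4L)
    stop("spline_fill needs >= 4 support points, got ", length(obs),
         call. = FALSE)
  lo <- obs[1]; hi <- obs[length(obs)]
  t <- s$t[lo:hi]; v <- s$v[lo:hi]
  gap <- is.na(v)
  if (any(gap)) {
    v[gap] <- stats::spline(x = t[!gap], y = v[!gap], xout = t[gap],
                            method = "natural")$y
  }
  out <- parameter_series(s$name, t, v, scale = s$scale,
                          provenance = s$provenance)
  with_provenance(out, "spline_fill")
}

#' Moving average with a time-defined window
#'
#' Replaces each value by the mean over `t - half_window .. t + half_window`
#' seconds, truncated at the series edges so the series keeps its length.
#' The window is defined in time, not in samples, so the smoothing is the
#' same on 10 ms and 100 ms grids.
#'
#' @param s A gap-free [parameter_series()].
#' @param half_window Half window width in seconds (default ±5 s).
#' @return A `parameter_series` with the moving-average flag set in its name.
#' @export
moving_average <- function(s, half_window = 5) {
  stopifnot(inherits(s, "parameter_series"))
  if (half_window <= 0) stop("half_window must be positive", call. = FALSE)
  stopifnot_gapfree(s, "moving_average")
  res <- series_resolution(s)
  h <- round(half_window * 1000 / res)
  n <- length(s$v)
  cs <- cumsum(c(0, s$v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  nm <- s$name; nm$mvavg <- TRUE
  out <- parameter_series(nm, s$t, v, scale = s$scale,
                          provenance = s$provenance)
  with_provenance(out, sprintf("moving_average(half_window=%gs)", half_window))
}

#' Rescale a series to the unit interval
#'
#' Maps the observed minimum to 0 and maximum to 1, the scaling used for the
#' similarity battery so that distance metrics are comparable across
#' parameters with different units. A constant series maps to all zeros with
#' a warning.
#'
#' @param s A gap-free [parameter_series()].
#' @return A `parameter_series` with `scale = "rescaled01"`.
#' @export
minmax_rescale <- function(s) {
  stopifnot(inherits(s, "parameter_series"))
  stopifnot_gapfree(s, "minmax_rescale")
  rng <- range(s$v)
  if (diff(rng) == 0) {
    warning("constant series rescaled to all zeros")
    v <- rep(0, length(s$v))
  } else {
    v <- (s$v - rng[1]) / (rng[2] - rng[1])
  }
  out <- parameter_series(s$name, s$t, v, scale = "rescaled01",
                          provenance = s$provenance)
  with_provenance(out, "minmax_rescale")
}

#' First-order Butterworth band filter
#'
#' Cascade of a first-order high-pass and a first-order low-pass Butterworth
#' filter (defaults 0.05 Hz and 0.5 Hz), applied forward-backward so the
#' filtered channel carries no phase lag into the cross-correlation
#' analysis. Used for the band-filtered skin-conductance variants.
#'
#' @param s A gap-free [parameter_series()].
#' @param hp High-pass cutoff in Hz.
#' @param lp Low-pass cutoff in Hz.
#' @param order Filter order of each stage (default 1).
#' @return A `parameter_series` with the filtered flag set in its name.
#' @export
butterworth_bandfilter <- function(s, hp = 0.05, lp = 0.5, order = 1) {
  stopifnot(inherits(s, "parameter_series"))
  stopifnot_gapfree(s, "butterworth_bandfilter")
  if (lp <= hp) stop("low-pass cutoff must exceed high-pass cutoff",
                     call. = FALSE)
  fs <- series_rate(s)
  if (fs <= 2 * lp)
    stop(sprintf("sampling rate %.3g Hz too low for low-pass at %g Hz",
                 fs, lp), call. = FALSE)
  bw_hp <- signal::butter(order, hp / (fs / 2), type = "high")
  bw_lp <- signal::butter(order, lp / (fs / 2), type = "low")
  v <- signal::filtfilt(bw_hp, s$v)
  v <- signal::filtfilt(bw_lp, v)
  nm <- s$name; nm$filtered <- TRUE
  out <- parameter_series(nm, s$t, v, scale = s$scale,
                          provenance = s$provenance)
  with_provenance(out, sprintf(
    "butterworth_bandfilter(hp=%gHz, lp=%gHz, order=%d, zero_phase)",
    hp, lp, order))
}
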