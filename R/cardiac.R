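#' Heart-rate-variability frequency band
#'
#' The three analysis bands of IBI fluctuation: very low frequency
#' (0.025-0.07 Hz), low frequency (0.07-0.14 Hz) and high frequency
#' (0.14-0.5 Hz).
#'
#' @param name One of `"VLF"`, `"LF"`, `"HF"`.
#' @return An object of class `hrv_band` with fields `name`, `f_lo`, `f_hi`.
#' @export
hrv_band <- function(name = c("VLF", "LF", "HF")) {
  name <- match.arg(name)
  edges <- switch(name,
                  VLF = c(0.025, 0.07),
                  LF  = c(0.07, 0.14),
                  HF  = c(0.14, 0.5))
  structure(list(name = name, f_lo = edges[1], f_hi = edges[2]),
            class = "hrv_band")
}

#' Detect R peaks in an ECG series
#'
#' Derivative-square-integrate detector: the ECG is band-passed (5-15 Hz,
#' zero phase), differentiated, squared and integrated over a 150 ms moving
#' window; R peaks are local maxima of the integrated energy above an
#' adaptive (amplitude-relative) threshold, separated by a 250 ms refractory
#' period. Peak times are refined to the maximum of the band-passed ECG near
#' each energy peak, so detection is invariant to a global amplitude scale.
#'
#' @param ecg A gap-free ECG [parameter_series()] sampled at >= 100 Hz.
#' @param threshold_frac Fraction of the robust peak-energy level used as
#'   detection threshold (default 0.2).
#' @return An object of class `r_peak_train` with fields `peak_times` (ms)
#'   and `source` (the ECG channel name). Empty, with a warning, for a
#'   flatline input.
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 0.2) {
  stopifnot(inherits(ecg, "parameter_series"))
  stopifnot_gapfree(ecg, "detect_r_peaks")
  fs <- series_rate(ecg)
  if (fs < 100) stop("ECG sampling rate must be >= 100 Hz, got ",
                     round(fs, 1), call. = FALSE)
  empty <- function() {
    warning("no QRS energy detected; returning empty peak train")
    structure(list(peak_times = numeric(0), source = format(ecg$name)),
              class = "r_peak_train")
  }
  if (stats::sd(ecg$v) == 0) return(empty())
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bp, ecg$v - mean(ecg$v))
  d <- c(0, diff(f)) * fs
  sq <- d^2
  w <- max(3L, round(0.150 * fs))
  u <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  u[is.na(u)] <- 0
  refr <- 0.250 * fs
  # local maxima of the integrated energy
  cand <- which(diff(sign(diff(u))) < 0) + 1L
  cand <- cand[u[cand] > 0]
  if (!length(cand)) return(empty())
  thr <- threshold_frac * stats::quantile(u[cand], 0.95, names = FALSE)
  cand <- cand[u[cand] >= thr]
  if (!length(cand)) return(empty())
  # enforce refractory period, keeping the strongest peak of each cluster
  cand <- cand[order(u[cand], decreasing = TRUE)]
  keep <- logical(0)
  acc <- integer(0)
  for (i in cand) {
    if (!length(acc) || all(abs(acc - i) >= refr)) acc <- c(acc, i)
  }
  acc <- sort(acc)
  # refine to the band-passed ECG maximum within +/-60 ms
  half <- as.integer(round(0.060 * fs))
  n <- length(f)
  refined <- vapply(acc, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(f[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  structure(list(peak_times = ecg$t[refined], source = format(ecg$name)),
            class = "r_peak_train")
}

#' @export
print.r_peak_train <- function(x, ...) {
  cat(sprintf("<r_peak_train> %d peaks from %s\n", length(x$peak_times),
              x$source))
  invisible(x)
}

#' Inter-beat intervals from an R-peak train
#'
#' IBI(t_i) = t_i - t_(i-1) in ms, stamped at the later peak. Intervals
#' outside the physiological range 250-3000 ms (missed or spurious beats)
#' are dropped with a message. The beat-stamped sequence is then resampled
#' onto a regular grid by natural cubic spline so it can enter the aligned
#' frame and the demodulation analysis.
#'
#' @param peaks An `r_peak_train` with at least 2 peaks.
#' @param platform Platform of the source ECG (for the derived channel
#'   name).
#' @param rate Output grid rate in Hz (default 4, at least twice the upper
#'   HF band edge).
#' @param bounds Physiological IBI bounds in ms.
#' @param resample If `FALSE`, return the beat-stamped irregular sequence as
#'   a two-column matrix instead of a gridded series.
#' @return A [parameter_series()] named `"IBI: from ECG <platform>"`.
#' @export
ibi_from_peaks <- function(peaks, platform, rate = 4,
                           bounds = c(250, 3000), resample = TRUE) {
  stopifnot(inherits(peaks, "r_peak_train"))
  if (length(peaks$peak_times) < 2L)
    stop("need >= 2 peaks to form intervals", call. = FALSE)
  ibi <- diff(peaks$peak_times)
  t <- peaks$peak_times[-1]
  ok <- ibi >= bounds[1] & ibi <= bounds[2]
  if (any(!ok))
    message(sum(!ok), " interval(s) outside [", bounds[1], ", ", bounds[2],
            "] ms dropped as artifacts")
  ibi <- ibi[ok]; t <- t[ok]
  if (!resample) return(cbind(t = t, ibi = ibi))
  if (length(t) < 4L)
    stop("too few valid intervals to resample", call. = FALSE)
  step <- 1000 / rate
  grid <- seq(ceiling(t[1] / step) * step, floor(t[length(t)] / step) * step,
              by = step)
  v <- stats::spline(x = t, y = ibi, xout = grid, method = "natural")$y
  nm <- channel_name("IBI", platform, derived_from = "ECG")
  out <- parameter_series(nm, grid, v)
  with_provenance(out, sprintf("ibi_from_peaks(rate=%gHz)", rate))
}

#' Convert between heart rate and inter-beat interval
#'
#' Uses the identity IBI \[ms\] = 60000 / HR \[bpm\] (and inversely); the
#' conversion is an involution, so applying it twice returns the input.
#'
#' @param v Positive numeric vector: HR in bpm or IBI in ms.
#' @return The converted values (IBI in ms for HR input and vice versa).
#' @examples
#' hr_ibi_convert(60)   # 1000 ms
#' hr_ibi_convert(1000) # 60 bpm
#' @export
hr_ibi_convert <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
    stop("hr_ibi_convert requires positive finite values", call. = FALSE)
  60000 / v
}

#' Band amplitude by complex demodulation
#'
#' Estimates the time-varying amplitude of IBI fluctuation inside one HRV
#' band: the (centred) series is multiplied by a complex carrier
#' exp(-2i*pi*fc*t) at the band centre fc = (f_lo + f_hi)/2, the product is
#' low-passed at half the band width (two zero-phase passes of a 4th-order
#' Butterworth — an 8th-order-equivalent response run as a stable cascade,
#' sharp enough that a tone at the neighbouring band's centre is rejected),
#' and the amplitude envelope is twice the modulus of the filtered product.
#'
#' @param ibi A gap-free, regularly sampled IBI [parameter_series()]
#'   (typically from [ibi_from_peaks()]).
#' @param band An [hrv_band()] or band name.
#' @param platform Platform for the derived channel name; defaults to the
#'   platform recorded in `ibi`'s name.
#' @return A `parameter_series` named `"<band>: from ECG <platform>"`
#'   holding the amplitude envelope in ms.
#' @export
complex_demodulation <- function(ibi, band, platform = NULL) {
  stopifnot(inherits(ibi, "parameter_series"))
  stopifnot_gapfree(ibi, "complex_demodulation")
  if (is.character(band)) band <- hrv_band(band)
  stopifnot(inherits(band, "hrv_band"))
  if (is.null(platform)) platform <- ibi$name$platform
  t_s <- ibi$t / 1000
  dur <- t_s[length(t_s)] - t_s[1]
  f_c <- (band$f_lo + band$f_hi) / 2
  if (dur < 2 / band$f_lo)
    stop(sprintf("series too short (%.1f s) for the %s band; need > %.1f s",
                 dur, band$name, 2 / band$f_lo), call. = FALSE)
  fs <- series_rate(ibi)
  half_bw <- (band$f_hi - band$f_lo) / 2
  z <- (ibi$v - mean(ibi$v)) * exp(-2i * pi * f_c * t_s)
  lp <- signal::butter(4, half_bw / (fs / 2), type = "low")
  re <- signal::filtfilt(lp, signal::filtfilt(lp, Re(z)))
  im <- signal::filtfilt(lp, signal::filtfilt(lp, Im(z)))
  amp <- 2 * sqrt(re^2 + im^2)
  nm <- channel_name(band$name, platform, derived_from = "ECG")
  out <- parameter_series(nm, ibi$t, amp)
  with_provenance(out, sprintf(
    "complex_demodulation(band=%s, fc=%.4gHz, lp=%.4gHz)",
    band$name, f_c, half_bw))
}
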