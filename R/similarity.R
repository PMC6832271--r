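#' Dynamic time warping distance
#'
#' Accumulated cost of the optimal monotone warping path between two
#' sequences under the absolute-difference local cost, with the standard
#' step set and anchored endpoints. No path-length normalization is applied
#' (the optimal path cost is summed as is), so values are comparable between
#' pairs of equal-length series; identical series have distance zero.
#' Intended for unit-interval rescaled signals so that distances share a
#' scale across parameters.
#'
#' @param x,y [parameter_series()] with `scale = "rescaled01"`, or plain
#'   numeric vectors; lengths >= 2.
#' @return Non-negative warping distance.
#' @export
dtw_distance <- function(x, y) {
  v <- similarity_inputs(x, y)
  cpp_dtw(v$x, v$y)
}

#' Global discrete Fréchet distance
#'
#' Minimum over monotone couplings of the maximum pointwise distance (the
#' shortest leash that lets two walkers traverse both curves in order).
#' Both series live on a shared time grid, so the leash length is measured
#' on values only (|a - b| at coupled indices); identical curves have
#' distance zero and the distance is never below the distance between the
#' (fixed-coupled) first points or last points.
#'
#' @inheritParams dtw_distance
#' @return Non-negative Fréchet distance.
#' @export
frechet_global <- function(x, y) {
  v <- similarity_inputs(x, y)
  cpp_frechet(v$x, v$y)
}

#' Moving-window local Fréchet profile
#'
#' [frechet_global()] evaluated on aligned sub-windows (default 1 min,
#' stepped every 10 s), revealing how similarity changes across activity
#' phases.
#'
#' @inheritParams dtw_distance
#' @param window Window length in seconds (default 60).
#' @param step Window step in seconds (default 10).
#' @return A data.frame of class `frechet_profile` with columns
#'   `window_start_s` and `distance`.
#' @export
frechet_local <- function(x, y, window = 60, step = 10) {
  v <- similarity_inputs(x, y, require_equal_length = TRUE)
  if (is.null(v$res_ms))
    stop("frechet_local needs parameter_series input (a time grid)",
         call. = FALSE)
  res_s <- v$res_ms / 1000
  w <- round(window / res_s)
  st <- max(1L, round(step / res_s))
  n <- length(v$x)
  if (w > n) stop("window longer than series span", call. = FALSE)
  starts <- seq.int(1L, n - w + 1L, by = st)
  d <- vapply(starts, function(i)
    cpp_frechet(v$x[i:(i + w - 1L)], v$y[i:(i + w - 1L)]), numeric(1))
  out <- data.frame(window_start_s = v$t0_s + (starts - 1L) * res_s,
                    distance = d)
  class(out) <- c("frechet_profile", "data.frame")
  out
}

similarity_inputs <- function(x, y, require_equal_length = FALSE) {
  res_ms <- NULL; t0_s <- 0
  if (inherits(x, "parameter_series")) {
    if (x$scale != "rescaled01" ||
        (inherits(y, "parameter_series") && y$scale != "rescaled01"))
      warning("similarity metrics expect rescaled01 series; ",
              "run minmax_rescale() first")
    res_ms <- series_resolution(x)
    t0_s <- x$t[1] / 1000
  }
  xv <- series_values(x); yv <- series_values(y)
  if (length(xv) == 0L || length(yv) == 0L)
    stop("empty series", call. = FALSE)
  if (length(xv) < 2L || length(yv) < 2L)
    stop("need series of length >= 2", call. = FALSE)
  if (anyNA(xv) || anyNA(yv))
    stop("similarity metrics require gap-free input", call. = FALSE)
  if (require_equal_length && length(xv) != length(yv))
    stop("series must share the grid", call. = FALSE)
  list(x = xv, y = yv, res_ms = res_ms, t0_s = t0_s)
}
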