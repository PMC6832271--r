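# Independent brute-force oracles. These deliberately avoid the dynamic
# programs used by the package: warping paths and couplings are enumerated
# explicitly, and the information-coefficient oracle scans every admissible
# grid by direct tabulation.

# all monotone paths from (1,1) to (n,m); returns min over paths of the
# accumulated |x_i - y_j| cost (DTW) or of the maximum cost (Frechet)
oracle_path_opt <- function(x, y, aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  n <- length(x); m <- length(y)
  best <- Inf
  rec <- function(i, j, acc) {
    c0 <- abs(x[i] - y[j])
    acc <- if (aggregate == "sum") acc + c0 else max(acc, c0)
    if (acc >= best) return(invisible())  # bound: both aggregates monotone
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
    invisible()
  }
  rec(1L, 1L, if (aggregate == "sum") 0 else -Inf)
  best
}

oracle_dtw <- function(x, y) oracle_path_opt(x, y, "sum")
oracle_frechet <- function(x, y) oracle_path_opt(x, y, "max")

# exhaustive MIC: every admissible grid (rows * cols <= n^alpha), every
# placement of cut points between distinct sorted values on both axes
oracle_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(n^alpha, 4)
  xs <- sort(unique(x)); ys <- sort(unique(y))
  xcutpool <- (xs[-length(xs)] + xs[-1]) / 2
  ycutpool <- (ys[-length(ys)] + ys[-1]) / 2
  best <- 0
  for (k in 2:floor(B / 2)) {
    for (l in 2:floor(B / k)) {
      if (length(xcutpool) < k - 1 || length(ycutpool) < l - 1) next
      xc <- utils::combn(length(xcutpool), k - 1)
      yc <- utils::combn(length(ycutpool), l - 1)
      for (a in seq_len(ncol(xc))) {
        xa <- findInterval(x, xcutpool[xc[, a]]) + 1L
        for (b in seq_len(ncol(yc))) {
          ya <- findInterval(y, ycutpool[yc[, b]]) + 1L
          counts <- tabulate(xa + k * (ya - 1L), nbins = k * l)
          p <- counts / n
          px <- tapply(p, rep(seq_len(k), l), sum)
          py <- tapply(p, rep(seq_len(l), each = k), sum)
          ep <- p * log2(p / (px[rep(seq_len(k), l)] *
                                py[rep(seq_len(l), each = k)]))
          mi <- sum(ep[p > 0])
          best <- max(best, mi / log2(min(k, l)))
        }
      }
    }
  }
  best
}

# small helper: a parameter series on a regular grid with a stock channel
make_series <- function(v, res_ms = 100, channel = channel_name("HR", "VP"),
                        t0 = 0, scale = "original") {
  parameter_series(channel, t0 + (seq_along(v) - 1) * res_ms, v,
                   scale = scale)
}

# synthetic ECG: Gaussian R waves at given peak times
make_ecg <- function(peak_s, fs = 250, dur = NULL, amp = 1, sigma_ms = 12,
                     noise_sd = 0) {
  if (is.null(dur)) dur <- max(peak_s) + 1
  t <- seq(0, dur, by = 1 / fs)
  v <- rnorm(length(t), 0, noise_sd)
  for (p in peak_s)
    v <- v + amp * exp(-((t - p)^2) / (2 * (sigma_ms / 1000)^2))
  parameter_series(channel_name("ECG", "VP"), t * 1000, v)
}
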