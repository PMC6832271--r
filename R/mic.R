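#' Maximal information coefficient (MIC)
#'
#' Normalized mutual information maximized over axis-aligned grids: over all
#' grids with `rows * cols <= n^alpha` (rows, cols >= 2), the mutual
#' information of the induced two-way table is divided by
#' `log2(min(rows, cols))` and the maximum is reported. MIC is 1 for any
#' noiseless functional relationship, near 0 for independent variables, and
#' depends on the data only through ranks, so it is invariant under strictly
#' monotone transforms of either variable.
#'
#' For each admissible grid shape the column axis is optimized exactly by a
#' dynamic program over clump boundaries (candidate cuts capped at
#' `c * cols` superclumps). The row axis is enumerated exhaustively when the
#' sample is small (`n <= exact_n`, where every row partition is visited),
#' and otherwise fixed to the mass equipartition of the search heuristic,
#' with both variable orderings tried and the maximum taken.
#'
#' @param x,y Equal-length numeric vectors or [parameter_series()] (n >= 25).
#' @param alpha Grid-size exponent: admissible grids satisfy
#'   `rows * cols <= n^alpha` (default 0.6).
#' @param c Clump factor: the column optimizer considers at most `c * cols`
#'   candidate cut points (default 15).
#' @param method `"auto"` (exact search for `n <= exact_n`, heuristic
#'   otherwise), `"exact"`, or `"approx"`.
#' @param exact_n Largest n for which `"auto"` uses the exhaustive row-axis
#'   search (default 40).
#' @return MIC in \[0, 1\]. Constant input gives 0 with a warning.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15,
                method = c("auto", "approx", "exact"), exact_n = 40) {
  method <- match.arg(method)
  x <- series_values(x); y <- series_values(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 25) stop("mic requires n >= 25, got ", n, call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (c < 1) stop("clump factor c must be >= 1", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; MIC = 0")
    return(0)
  }
  B <- max(n^alpha, 4)
  if (method == "auto") method <- if (n <= exact_n) "exact" else "approx"
  l_max <- floor(B / 2)
  best <- 0
  if (method == "exact") {
    for (l in 2:l_max) {
      kmax <- floor(B / l)
      best <- max(best, mic_exact_shape(x, y, l, kmax))
    }
  } else {
    for (orient in 1:2) {
      a <- if (orient == 1) x else y
      b <- if (orient == 1) y else x
      ord <- order(a)
      xg <- cumsum(c(1L, diff(a[ord]) != 0))
      b_sorted_rank <- b[ord]
      for (l in 2:l_max) {
        kmax <- floor(B / l)
        q <- mic_equipartition(b_sorted_rank, l)
        chat <- max(as.integer(round(c * kmax)), kmax, 2L)
        I <- cpp_mine_optimize(q, xg, l, kmax, chat)
        for (k in 2:kmax)
          best <- max(best, I[k] / log2(min(k, l)))
      }
    }
  }
  min(best, 1)
}

# exhaustive search over every row partition of one shape (l rows), columns
# optimized by the exact DP with all clump boundaries as candidates
mic_exact_shape <- function(x, y, l, kmax) {
  ord <- order(x)
  xg <- cumsum(c(1L, diff(x[ord]) != 0))
  yo <- y[ord]
  y_sorted <- sort(unique(y))
  gaps <- length(y_sorted) - 1L
  if (gaps < l - 1L) return(0)
  cuts <- utils::combn(gaps, l - 1L)
  n <- length(y)
  best <- 0
  norm <- log2(pmin(2:kmax, l))
  for (j in seq_len(ncol(cuts))) {
    brk <- c(-Inf, (y_sorted[cuts[, j]] + y_sorted[cuts[, j] + 1L]) / 2, Inf)
    q <- as.integer(cut(yo, breaks = brk))
    I <- cpp_mine_optimize(q, xg, l, kmax, n)
    best <- max(best, max(I[2:kmax] / norm))
  }
  best
}

# mass equipartition of sorted-by-x row values into l rows, never splitting
# ties; greedy with running re-estimation of the desired row size
mic_equipartition <- function(b, l) {
  n <- length(b)
  ordb <- order(b)
  grp <- rle(as.numeric(b[ordb]))$lengths
  row_of_group <- integer(length(grp))
  row <- 1L; cnt <- 0; rem_points <- n; rem_rows <- l
  for (g in seq_along(grp)) {
    desired <- rem_points / rem_rows
    if (cnt > 0 && row < l &&
        abs(cnt + grp[g] - desired) > abs(cnt - desired)) {
      row <- row + 1L; rem_rows <- rem_rows - 1L; cnt <- 0
    }
    row_of_group[g] <- row
    cnt <- cnt + grp[g]
    rem_points <- rem_points - grp[g]
  }
  q <- integer(n)
  q[ordb] <- rep.int(row_of_group, grp)
  q
}

series_values <- function(x) {
  if (inherits(x, "parameter_series")) x$v else as.numeric(x)
}
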