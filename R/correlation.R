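#' Coefficient of determination of a pairwise linear fit
#'
#' Squared Pearson correlation of the two channels, identical to the R
#' squared of the ordinary least-squares fit of one on the other; the share
#' of variance a linear model explains. Computed on original-scale signals.
#'
#' @param x,y Equal-length numeric vectors or [parameter_series()]
#'   (length >= 3, gap-free).
#' @return R squared in \[0, 1\], or `NA` with a warning for zero-variance
#'   input.
#' @export
linear_r2 <- function(x, y) {
  x <- series_values(x); y <- series_values(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need length >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("linear_r2 requires gap-free input",
                                 call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; R squared undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

# MacKinnon (1994) response-surface coefficients for the p-value of the
# constant-only unit-root t statistic (values as tabulated in standard
# econometrics software)
.ADF_TAU_STAR <- -1.61
.ADF_TAU_MIN <- -18.83
.ADF_TAU_MAX <- 2.74
.ADF_SMALLP <- c(2.1659, 1.4412, 0.038269)
.ADF_LARGEP <- c(1.7339, 0.93202, -0.12745, -0.010368)

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root regression with constant:
#' `diff(y)_t = a + b * y_(t-1) + sum_i g_i * diff(y)_(t-i) + e_t`,
#' with the augmentation order chosen by AIC up to the Schwert rule-of-thumb
#' maximum. The t statistic of `b` is mapped to a p-value through the
#' MacKinnon (1994) response surface; the series is called stationary when
#' the unit root is rejected at level `alpha`. A constant series is
#' stationary by convention.
#'
#' @param x Numeric vector or [parameter_series()], n >= 20.
#' @param alpha Rejection level (default 0.05).
#' @param max_lag Maximum augmentation order; default
#'   `floor(12 * (n/100)^0.25)`.
#' @return List with `stationary` (logical), `p`, `tau`, `lag` and `n`.
#' @export
adf_stationary <- function(x, alpha = 0.05, max_lag = NULL) {
  y <- series_values(x)
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 20) stop("adf_stationary requires n >= 20", call. = FALSE)
  if (stats::sd(y) == 0) {
    message("constant series: stationary by convention")
    return(list(stationary = TRUE, p = 0, tau = -Inf, lag = 0L, n = n))
  }
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  max_lag <- min(max_lag, floor(n / 2) - 2L)
  dy <- diff(y)
  m <- length(dy)
  # common estimation sample across candidate lag orders so AIC is comparable
  idx <- (max_lag + 1L):m
  resp <- dy[idx]
  ylag <- y[idx]
  lagmat <- if (max_lag > 0)
    vapply(seq_len(max_lag), function(i) dy[idx - i], numeric(length(idx)))
  else NULL
  nn <- length(resp)
  best <- NULL
  for (p in 0:max_lag) {
    X <- cbind(1, ylag)
    if (p > 0) X <- cbind(X, lagmat[, seq_len(p), drop = FALSE])
    fit <- stats::lm.fit(X, resp)
    rss <- sum(fit$residuals^2)
    k <- ncol(X) + 1  # + error variance
    aic <- nn * (log(2 * pi) + log(rss / nn) + 1) + 2 * k
    if (is.null(best) || aic < best$aic)
      best <- list(aic = aic, fit = fit, p = p, X = X, rss = rss)
  }
  sigma2 <- best$rss / (nn - ncol(best$X))
  xtx_inv <- chol2inv(best$fit$qr$qr[seq_len(ncol(best$X)), , drop = FALSE])
  tau <- best$fit$coefficients[2] / sqrt(sigma2 * xtx_inv[2, 2])
  pval <- adf_mackinnon_p(unname(tau))
  list(stationary = pval < alpha, p = pval, tau = unname(tau),
       lag = best$p, n = n)
}

adf_mackinnon_p <- function(tau) {
  if (tau > .ADF_TAU_MAX) return(1)
  if (tau < .ADF_TAU_MIN) return(0)
  co <- if (tau <= .ADF_TAU_STAR) .ADF_SMALLP else .ADF_LARGEP
  z <- sum(co * tau^(seq_along(co) - 1L))
  stats::pnorm(z)
}

#' Lagged cross-correlation with stationarity handling
#'
#' Pearson correlation between `x` at time t and `y` at time t + lag, for
#' integer-second lags up to `max_lag` (default -15..+15 s). Because raw
#' physiological series are trend-dominated, both series are first
#' differenced (at most `max_diff` times) until the augmented Dickey-Fuller
#' test accepts stationarity for both. A positive best lag means `y` lags
#' behind `x`; `x` plays the role of the independent (reference) series.
#'
#' @param x,y [parameter_series()] on a shared grid, or plain numeric
#'   vectors (then `rate` gives samples per second).
#' @param max_lag Maximum lag in seconds (default 15).
#' @param difference If `TRUE` (default), difference to stationarity.
#' @param max_diff Differencing cap (default 2); if both series are still
#'   non-stationary at the cap, coefficients are computed on the capped
#'   differences and flagged.
#' @param alpha Level for the stationarity test.
#' @param rate Samples per second, required for plain numeric input.
#' @param min_overlap Minimum overlapping samples per lag (default 30);
#'   shorter overlaps give a missing coefficient.
#' @return An object of class `cross_correlation`: per-lag coefficients,
#'   `best_lag` (s), `best_r`, differencing order used, and a
#'   `stationarity_attained` flag.
#' @export
cross_correlation <- function(x, y, max_lag = 15, difference = TRUE,
                              max_diff = 2, alpha = 0.05, rate = NULL,
                              min_overlap = 30) {
  if (inherits(x, "parameter_series")) {
    if (!inherits(y, "parameter_series") || length(x$t) != length(y$t) ||
        any(x$t != y$t))
      stop("x and y must share the same grid", call. = FALSE)
    rate <- series_rate(x)
    xv <- x$v; yv <- y$v
  } else {
    if (is.null(rate)) stop("rate required for plain numeric input",
                            call. = FALSE)
    xv <- as.numeric(x); yv <- as.numeric(series_values(y))
  }
  if (anyNA(xv) || anyNA(yv))
    stop("cross_correlation requires gap-free input", call. = FALSE)
  step <- rate  # samples per 1 s lag step
  if (abs(step - round(step)) > 1e-8)
    stop("grid must contain an integer number of samples per second",
         call. = FALSE)
  step <- as.integer(round(step))
  d <- 0L
  attained <- TRUE
  if (difference) {
    repeat {
      sx <- adf_stationary(xv, alpha = alpha)$stationary
      sy <- adf_stationary(yv, alpha = alpha)$stationary
      if (sx && sy) break
      if (d >= max_diff) { attained <- FALSE; break }
      xv <- diff(xv); yv <- diff(yv); d <- d + 1L
    }
  }
  n <- length(xv)
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    k <- l * step
    if (k >= 0) {
      if (n - k < min_overlap) return(NA_real_)
      a <- xv[seq_len(n - k)]; b <- yv[seq_len(n - k) + k]
    } else {
      k <- -k
      if (n - k < min_overlap) return(NA_real_)
      a <- xv[seq_len(n - k) + k]; b <- yv[seq_len(n - k)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  best_lag <- NA_integer_; best_r <- NA_real_
  if (any(!is.na(r))) {
    mx <- max(r, na.rm = TRUE)
    cand <- lags[!is.na(r) & r == mx]
    best_lag <- cand[which.min(abs(cand))]  # prefer the smallest shift on ties
    best_r <- mx
  }
  structure(
    list(lags = lags, coefficients = r, best_lag = best_lag, best_r = best_r,
         differenced = d, stationarity_attained = attained, n = n),
    class = "cross_correlation"
  )
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat(sprintf(
    "<cross_correlation> best lag %+d s (r = %.3f), diff order %d%s\n",
    x$best_lag, x$best_r, x$differenced,
    if (x$stationarity_attained) "" else " [stationarity not attained]"))
  invisible(x)
}

#' Classify a pairwise association from MIC and R squared
#'
#' The nonlinearity score MIC - R^2 separates three regimes: a strongly
#' negative score marks a "false" linear relationship (the linear fit is not
#' confirmed by the information coefficient), a score near zero a "true"
#' linear relationship, and a positive score a functional but nonlinear
#' relationship.
#'
#' @param mic_val,r2_val Values in \[0, 1\].
#' @param epsilon Half-width of the "near zero" band (default 0.1).
#' @return An object of class `association_class` with fields `value`
#'   (`"false_linear"`, `"true_linear"` or `"nonlinear_functional"`),
#'   `score` and `epsilon`.
#' @examples
#' classify_association(0.2, 0.91)  # score -0.71: false linear
#' @export
classify_association <- function(mic_val, r2_val, epsilon = 0.1) {
  stopifnot(is.finite(mic_val), is.finite(r2_val),
            mic_val >= 0, mic_val <= 1, r2_val >= 0, r2_val <= 1,
            epsilon > 0)
  score <- mic_val - r2_val
  value <- if (score < -epsilon) "false_linear"
           else if (score > epsilon) "nonlinear_functional"
           else "true_linear"
  structure(list(value = value, score = score, epsilon = epsilon),
            class = "association_class")
}

#' @export
print.association_class <- function(x, ...) {
  cat(sprintf("<association> %s (MIC - R2 = %+.3f, epsilon = %g)\n",
              x$value, x$score, x$epsilon))
  invisible(x)
}

#' Cluster pair profiles of MIC values
#'
#' k-means over per-pair MIC profiles (pairs x participants), with clusters
#' relabelled `low`/`moderate`/`high` by ascending centroid mean so the
#' labels are stable across runs. Missing cells are imputed with the pair
#' mean before clustering; distances are Euclidean on the raw profiles (MIC
#' is already on \[0, 1\]).
#'
#' @param profile_matrix Numeric matrix, rows = pairs, columns =
#'   participants.
#' @param k Number of clusters (default 3: low, moderate, high).
#' @param seed Optional integer seed for reproducible restarts.
#' @param nstart Random restarts (default 25; best inertia kept).
#' @return List with `labels` (factor per pair, ordered levels), `centers`,
#'   and the `kmeans` fit. Degenerate input with fewer distinct profiles
#'   than `k` collapses to a single cluster with a warning.
#' @export
cluster_pairs <- function(profile_matrix, k = 3, seed = NULL, nstart = 25) {
  m <- as.matrix(profile_matrix)
  if (nrow(m) < k) stop("fewer pairs than clusters", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (all(miss)) stop("pair ", i, " has no observed cells", call. = FALSE)
    m[i, miss] <- mean(m[i, !miss])
  }
  lv <- if (k == 3) c("low", "moderate", "high") else
    paste0("cluster_", seq_len(k))
  if (nrow(unique(m)) < k) {
    warning("fewer distinct profiles than clusters; single effective cluster")
    labels <- factor(rep(lv[1], nrow(m)), levels = lv)
    names(labels) <- rownames(m)
    return(list(labels = labels, centers = matrix(colMeans(m), nrow = 1),
                fit = NULL))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fit <- stats::kmeans(m, centers = k, nstart = nstart)
  ord <- order(rowMeans(fit$centers))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- factor(lv[relabel[fit$cluster]], levels = lv)
  names(labels) <- rownames(m)
  list(labels = labels, centers = fit$centers[ord, , drop = FALSE], fit = fit)
}
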