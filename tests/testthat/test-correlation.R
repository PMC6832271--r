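test_that("linear_r2 matches the OLS coefficient of determination", {
  x <- seq_len(50)
  expect_equal(linear_r2(x, 2 * x + 1), 1)
  # y = x^2 on a symmetric grid: odd-even orthogonality gives R2 ~ 0
  xs <- seq(-3, 3, length.out = 61)
  expect_lt(linear_r2(xs, xs^2), 1e-20)
  # agrees with lm() on arbitrary data
  set.seed(14)
  a <- rnorm(100); b <- 0.5 * a + rnorm(100)
  expect_equal(linear_r2(a, b), summary(stats::lm(b ~ a))$r.squared)
  expect_warning(na <- linear_r2(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(na))
})

test_that("the unit-root test separates noise, random walks and trends", {
  set.seed(31)
  wn <- replicate(20, adf_stationary(rnorm(500))$stationary)
  expect_gte(mean(wn), 0.95)
  rw <- replicate(20, adf_stationary(cumsum(rnorm(500)))$stationary)
  expect_lte(mean(rw), 0.2)
  ramp <- replicate(10, adf_stationary(seq(0, 10, length.out = 300) +
                                         rnorm(300, 0, 0.01))$stationary)
  expect_lte(mean(ramp), 0.2)
  expect_message(cs <- adf_stationary(rep(2, 50)), "constant")
  expect_true(cs$stationary)
  expect_error(adf_stationary(rnorm(10)), "n >= 20")
})

test_that("cross-correlation recovers constructed shifts", {
  set.seed(41)
  n <- 2000
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), n + 2))
  y <- c(rep(0, 2), x[seq_len(n - 2)])
  x <- x[seq_len(n)]
  cc <- cross_correlation(x, y, rate = 1)
  expect_equal(cc$best_lag, 2)
  expect_gt(cc$best_r, 0.99)
  # identity: peak 1 at lag 0
  cc0 <- cross_correlation(x, x, rate = 1)
  expect_equal(cc0$best_lag, 0)
  expect_equal(cc0$best_r, 1)
  expect_true(all(cc0$coefficients >= -1 & cc0$coefficients <= 1,
                  na.rm = TRUE))
})

test_that("cross-correlation differences a trending pair to stationarity", {
  set.seed(42)
  n <- 1200
  base <- cumsum(rnorm(n))
  x <- base + rnorm(n, 0, 0.1)
  y <- c(rep(0, 1), base[seq_len(n - 1)]) + rnorm(n, 0, 0.1)
  cc <- cross_correlation(x, y, rate = 1)
  expect_gte(cc$differenced, 1)
  expect_true(cc$stationarity_attained)
  expect_equal(cc$best_lag, 1)
})

test_that("cross-correlation mirrors under argument swap", {
  set.seed(43)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 800))
  y <- as.numeric(stats::arima.sim(list(ar = 0.5), 800))
  ab <- cross_correlation(x, y, rate = 1, difference = FALSE)
  ba <- cross_correlation(y, x, rate = 1, difference = FALSE)
  expect_equal(ab$coefficients, rev(ba$coefficients), tolerance = 1e-12)
})

test_that("independent pairs show no spurious lag structure", {
  set.seed(44)
  cc <- cross_correlation(rnorm(10000), rnorm(10000), rate = 1)
  expect_lt(max(abs(cc$coefficients), na.rm = TRUE), 0.1)
})

test_that("lag overlap shorter than the minimum yields missing coefficients", {
  set.seed(45)
  cc <- cross_correlation(rnorm(40), rnorm(40), rate = 1, difference = FALSE)
  expect_true(all(is.na(cc$coefficients[abs(cc$lags) > 10])))
  expect_true(any(!is.na(cc$coefficients)))
})

test_that("association classes partition the score range", {
  cls <- classify_association(0.2, 0.91)
  expect_equal(cls$score, -0.71)
  expect_identical(cls$value, "false_linear")
  expect_identical(classify_association(0.5, 0.5)$value, "true_linear")
  expect_identical(classify_association(0.9, 0.1)$value,
                   "nonlinear_functional")
  # exhaustive and exclusive over a grid of (mic, r2) for several epsilon
  for (eps in c(0.05, 0.1, 0.3)) {
    grid <- expand.grid(m = seq(0, 1, by = 0.1), r = seq(0, 1, by = 0.1))
    vals <- mapply(function(m, r)
      classify_association(m, r, eps)$value, grid$m, grid$r)
    expect_true(all(vals %in% c("false_linear", "true_linear",
                                "nonlinear_functional")))
    score <- grid$m - grid$r
    expect_identical(unname(vals[score < -eps - 1e-12]),
                     rep("false_linear", sum(score < -eps - 1e-12)))
    expect_identical(unname(vals[score > eps + 1e-12]),
                     rep("nonlinear_functional", sum(score > eps + 1e-12)))
  }
})

test_that("false nonlinear discoveries are rare on independent pairs", {
  # the MIC null shrinks slowly with sample size; 3000 points bring its
  # 90th percentile under the default epsilon of 0.1
  set.seed(46)
  hits <- replicate(12, {
    x <- runif(3000); y <- runif(3000)
    classify_association(mic(x, y), linear_r2(x, y))$value ==
      "nonlinear_functional"
  })
  expect_lt(mean(hits), 0.10)
})

test_that("k-means pair clustering recovers separated profiles", {
  set.seed(51)
  blob <- function(center, n) matrix(pmin(pmax(
    rnorm(n * 6, center, 0.03), 0), 1), nrow = n)
  m <- rbind(blob(0.1, 4), blob(0.5, 4), blob(0.9, 4))
  rownames(m) <- paste0("pair", 1:12)
  cl <- cluster_pairs(m, k = 3, seed = 9)
  expect_identical(as.character(cl$labels),
                   rep(c("low", "moderate", "high"), each = 4))
  # label assignment is invariant to row permutation
  perm <- sample(12)
  cl2 <- cluster_pairs(m[perm, ], k = 3, seed = 9)
  expect_identical(as.character(cl2$labels),
                   as.character(cl$labels)[perm])
  # missing cells are imputed with the pair mean, not dropped
  m2 <- m; m2[1, 2] <- NA
  expect_identical(as.character(cluster_pairs(m2, k = 3, seed = 9)$labels),
                   as.character(cl$labels))
  expect_warning(deg <- cluster_pairs(matrix(0.4, 5, 4), k = 3),
                 "single effective cluster")
  expect_equal(length(unique(deg$labels)), 1L)
  expect_error(cluster_pairs(m[1:2, ], k = 3), "fewer pairs")
})
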