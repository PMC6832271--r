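test_that("spline_fill fills gaps, trims edges, and keeps observed samples", {
  # no gaps: identity on values
  s <- make_series(c(1, 4, 2, 8, 5, 7))
  expect_equal(spline_fill(s)$v, s$v)

  # collinear support: the spline through points on a line is the line
  v <- 2 * (0:9)
  v[5] <- NA
  filled <- spline_fill(make_series(v))
  expect_equal(filled$v, 2 * (0:9))

  # respiratory-band sinusoid sampled at 4 Hz, one missing cell: the
  # filled value stays within 1% of the generating function
  t_s <- seq(0, 8, by = 0.25)
  true <- sin(2 * pi * 0.25 * t_s)
  v2 <- true
  v2[9] <- NA
  filled2 <- spline_fill(make_series(v2, res_ms = 250))
  expect_lt(abs(filled2$v[9] - true[9]), 0.01 * max(abs(true)))
  # observed samples are bit-identical
  expect_identical(filled2$v[-9], true[-9])

  # leading/trailing gaps are trimmed to the observed span
  v3 <- c(NA, NA, 1, 2, NA, 4, 5, NA)
  f3 <- spline_fill(make_series(v3))
  expect_equal(length(f3$v), 5)
  expect_false(anyNA(f3$v))

  expect_error(spline_fill(make_series(c(1, NA, 2, NA, 3))), ">= 4 support")
  expect_error(spline_fill(make_series(rep(NA_real_, 10))), "all-missing")
})

test_that("moving_average uses a truncated time window", {
  expect_equal(moving_average(make_series(rep(3, 50)))$v, rep(3, 50))

  # unit spike on a 100 ms grid with a +/-5 s window: plateau of 1/101
  v <- rep(0, 300); v[150] <- 1
  ma <- moving_average(make_series(v), half_window = 5)
  # brute-force oracle: windowed means over [t-5s, t+5s]
  t <- (0:299) * 100
  oracle <- vapply(seq_along(v), function(i)
    mean(v[t >= t[i] - 5000 & t <= t[i] + 5000]), numeric(1))
  expect_equal(ma$v, oracle)
  expect_equal(ma$v[150], 1 / 101)
  expect_equal(ma$v[120], 1 / 101)  # anywhere within +/-50 cells

  # linear ramp: interior points unchanged under a symmetric window
  ramp <- seq(0, 10, length.out = 201)
  mr <- moving_average(make_series(ramp), half_window = 2)
  interior <- 30:170
  expect_equal(mr$v[interior], ramp[interior])
  expect_true(mr$name$mvavg)
  expect_error(moving_average(make_series(ramp), half_window = 0),
               "positive")
})

test_that("minmax_rescale maps min/max to 0/1 and is idempotent", {
  r <- minmax_rescale(make_series(c(2, 4, 6)))
  expect_equal(r$v, c(0, 0.5, 1))
  expect_equal(r$scale, "rescaled01")
  expect_equal(minmax_rescale(r)$v, r$v)
  expect_warning(cz <- minmax_rescale(make_series(c(5, 5, 5))), "constant")
  expect_equal(cz$v, c(0, 0, 0))
  set.seed(3)
  v <- rnorm(100)
  rr <- minmax_rescale(make_series(v))$v
  expect_true(all(rr >= 0 & rr <= 1))
})

test_that("moving_average then minmax_rescale is invariant to re-unitting", {
  set.seed(8)
  v <- cumsum(rnorm(200))
  base <- minmax_rescale(moving_average(make_series(v)))
  for (ab in list(c(2, 5), c(0.1, -3), c(1000, 1e5))) {
    re <- minmax_rescale(moving_average(make_series(ab[1] * v + ab[2])))
    expect_equal(re$v, base$v, tolerance = 1e-10)
  }
})

test_that("the band filter kills DC and attenuates per its magnitude response", {
  fs <- 10  # Hz
  t <- seq(0, 120, by = 1 / fs)
  # constant input: the high-pass removes DC entirely
  dc <- butterworth_bandfilter(make_series(rep(4, length(t)), res_ms = 100))
  expect_lt(max(abs(dc$v[500:700])), 1e-6)

  amp_ratio <- function(freq, fs, n_per = 20) {
    tt <- seq(0, n_per / freq, by = 1 / fs)
    s <- make_series(sin(2 * pi * freq * tt), res_ms = 1000 / fs)
    out <- butterworth_bandfilter(s)
    mid <- seq(round(length(tt) * 0.3), round(length(tt) * 0.7))
    max(abs(out$v[mid]))
  }
  # 0.15 Hz is in band: attenuation under 3 dB
  expect_gt(amp_ratio(0.15, fs = 10), 10^(-3 / 20))
  # 5 Hz at 25 Hz sampling is 10x the low-pass corner: over 20 dB down
  expect_lt(amp_ratio(5, fs = 25), 10^(-20 / 20))

  expect_error(butterworth_bandfilter(make_series(rnorm(100)),
                                      hp = 0.5, lp = 0.05), "must exceed")
  expect_error(butterworth_bandfilter(make_series(rnorm(100), res_ms = 1500)),
               "too low")
  expect_true(butterworth_bandfilter(make_series(rnorm(100)))$name$filtered)
})
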