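test_that("R-peak detection recovers a clean pulse train to one sample", {
  set.seed(21)
  truth_peaks <- cumsum(runif(60, 0.8, 1.2))
  ecg <- make_ecg(truth_peaks, fs = 250)
  pk <- detect_r_peaks(ecg)
  expect_equal(length(pk$peak_times), length(truth_peaks))
  err_ms <- abs(pk$peak_times - truth_peaks * 1000)
  expect_lt(max(err_ms), 1000 / 250)  # under one sample

  # the adaptive threshold makes detection amplitude-invariant
  half <- ecg; half$v <- ecg$v * 0.5
  pk_half <- detect_r_peaks(half)
  expect_equal(length(pk_half$peak_times), length(truth_peaks))

  flat <- make_series(rep(0, 1000), res_ms = 4, channel_name("ECG", "VP"))
  expect_warning(pk0 <- detect_r_peaks(flat), "empty peak train")
  expect_length(pk0$peak_times, 0)
})

test_that("peak-count conservation holds on noisy synthetic ECG", {
  set.seed(22)
  truth_peaks <- cumsum(runif(50, 0.7, 1.1))
  ecg <- make_ecg(truth_peaks, fs = 250, noise_sd = 0.05)
  expect_equal(length(detect_r_peaks(ecg)$peak_times), length(truth_peaks))
})

test_that("inter-beat intervals follow from peak gaps with artifact filtering", {
  pk <- structure(list(peak_times = c(0, 1000, 2000), source = "ECG: VP"),
                  class = "r_peak_train")
  expect_equal(ibi_from_peaks(pk, "VP", resample = FALSE)[, "ibi"],
               c(1000, 1000))
  pk2 <- structure(list(peak_times = c(0, 800, 1700), source = "ECG: VP"),
                   class = "r_peak_train")
  expect_equal(ibi_from_peaks(pk2, "VP", resample = FALSE)[, "ibi"],
               c(800, 900))
  # a 100 ms artifact gap is dropped; remaining intervals untouched
  pk3 <- structure(list(peak_times = c(0, 800, 900, 1700, 2500),
                        source = "ECG: VP"),
                   class = "r_peak_train")
  expect_message(out <- ibi_from_peaks(pk3, "VP", resample = FALSE),
                 "artifact")
  expect_equal(unname(out[, "ibi"]), c(800, 800, 800))
  expect_error(ibi_from_peaks(structure(list(peak_times = 5,
                                             source = "x"),
                                        class = "r_peak_train"), "VP"),
               ">= 2 peaks")
})

test_that("HR/IBI conversion uses 60000 and is an involution", {
  expect_equal(hr_ibi_convert(60), 1000)
  expect_equal(hr_ibi_convert(120), 500)
  expect_equal(hr_ibi_convert(hr_ibi_convert(73.2)), 73.2)
  set.seed(2)
  v <- runif(50, 40, 3000)
  expect_equal(hr_ibi_convert(hr_ibi_convert(v)), v)
  expect_error(hr_ibi_convert(0), "positive")
  expect_error(hr_ibi_convert(-5), "positive")
})

test_that("complex demodulation recovers in-band amplitude and rejects others", {
  t_s <- seq(0, 600, by = 0.25)
  nm <- channel_name("IBI", "VP", derived_from = "ECG")
  tone <- parameter_series(nm, t_s * 1000,
                           900 + 50 * sin(2 * pi * 0.105 * t_s))
  lf <- complex_demodulation(tone, "LF")
  mid <- which(t_s > 60 & t_s < 540)
  expect_lt(abs(stats::median(lf$v[mid]) - 50), 0.05 * 50)
  hf <- complex_demodulation(tone, "HF")
  expect_lt(stats::median(hf$v[mid]), 5)
  flat <- parameter_series(nm, t_s * 1000, rep(900, length(t_s)))
  for (b in c("VLF", "LF", "HF"))
    expect_lt(max(complex_demodulation(flat, b)$v), 1e-6)
  short <- parameter_series(nm, seq(0, 30, by = 0.25) * 1000, rnorm(121))
  expect_error(complex_demodulation(short, "VLF"), "too short")
})

test_that("two-tone input separates into its per-band amplitudes", {
  t_s <- seq(0, 900, by = 0.25)
  nm <- channel_name("IBI", "BH", derived_from = "ECG")
  a_lf <- 50; a_hf <- 50
  two <- parameter_series(nm, t_s * 1000,
                          900 + a_lf * sin(2 * pi * 0.105 * t_s) +
                            a_hf * sin(2 * pi * 0.32 * t_s))
  mid <- which(t_s > 90 & t_s < 810)
  lf <- stats::median(complex_demodulation(two, "LF")$v[mid])
  hf <- stats::median(complex_demodulation(two, "HF")$v[mid])
  expect_lt(abs(lf - a_lf), 0.1 * a_lf)
  expect_lt(abs(hf - a_hf), 0.1 * a_hf)
  # band naming follows the derived-channel grammar
  expect_identical(format(complex_demodulation(two, "LF")$name),
                   "LF: from ECG BH")
})

test_that("HRV band edges match the analysis definition", {
  expect_equal(unlist(hrv_band("VLF")[c("f_lo", "f_hi")]),
               c(f_lo = 0.025, f_hi = 0.07))
  expect_equal(unlist(hrv_band("LF")[c("f_lo", "f_hi")]),
               c(f_lo = 0.07, f_hi = 0.14))
  expect_equal(unlist(hrv_band("HF")[c("f_lo", "f_hi")]),
               c(f_lo = 0.14, f_hi = 0.5))
})
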