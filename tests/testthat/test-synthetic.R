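test_that("the protocol encodes the stepped ergometer session", {
  ph <- protocol_phases()
  expect_equal(nrow(ph), 7)
  expect_equal(ph$load, c(0, 35, 65, 100, 133, 165, 0))
  expect_equal(max(ph$start + ph$duration), 1200)
  expect_equal(ph$duration[2:6], rep(120, 5))
  expect_equal(ph$start[1], 0)
  expect_equal(ph$duration[c(1, 7)], c(300, 300))
})

test_that("truth trajectories respond to load and stay consistent", {
  tr <- simulate_truth(101)
  # cycling raises heart rate over rest
  hr_at <- function(t) tr$hr[which.min(abs(tr$t_s - t))]
  expect_gt(hr_at(895), hr_at(295))
  # HR and IBI are exact reciprocals (60000 constant)
  expect_equal(tr$ibi, 60000 / tr$hr, tolerance = 1e-12)
  expect_true(all(tr$hr >= 45 & tr$hr <= 200))
  expect_true(all(tr$gsr_tonic > 0))
  # beat gaps track the local IBI
  gaps <- diff(tr$peak_times_ms)
  expect_true(all(gaps > 250 & gaps < 3000))
  # determinism
  expect_identical(simulate_truth(101), tr)
})

test_that("a zero-load, modulation-free protocol is an equilibrium", {
  ph <- protocol_phases()
  ph$load <- 0
  tr <- simulate_truth(5, phases = ph,
                       params = truth_params(lf_amp_ms = 0, hf_amp_ms = 0,
                                             gsr_event_rate = 1e-9))
  expect_lt(diff(range(tr$hr)), 1e-9)
  expect_lt(diff(range(tr$gsr_tonic)), 1e-9)
})

test_that("sensor models apply sampling, lag, offset and dropout", {
  tr <- simulate_truth(7, params = truth_params(lf_amp_ms = 0,
                                                hf_amp_ms = 0))
  # identity model: stream equals sampled truth
  m0 <- sensor_error_model("VP", rate = 4)
  s0 <- apply_sensor_model(tr, m0, "HR", seed = 1)
  expect_equal(s0$v, stats::approx(tr$t_s, tr$hr, xout = s0$t / 1000)$y,
               tolerance = 1e-12)
  # reciprocal offset is maximal in the low range
  mo <- sensor_error_model("BH", rate = 4, offset_a = 300)
  so <- apply_sensor_model(tr, mo, "HR", seed = 1)
  offs <- so$v - s0$v
  # offset follows the reciprocal law exactly: large at low HR, small at high
  expect_equal(offs, 300 / s0$v, tolerance = 1e-9)
  expect_gt(offs[which.min(s0$v)], offs[which.max(s0$v)])
  # dropout removes about the configured share of samples
  md <- sensor_error_model("E4", rate = 64, dropout_p = 0.2)
  sd_ <- apply_sensor_model(tr, md, "IBI", seed = 2)
  expect_lt(length(sd_$t) / (64 * 1200), 0.85)
  # unsupported combination refused
  expect_error(apply_sensor_model(tr, md, "HR"), "does not measure")
})

test_that("a lagged sensor model is recovered by the cross-correlation", {
  tr <- simulate_truth(8)
  ref <- apply_sensor_model(tr, sensor_error_model("VP", rate = 4,
                                                   noise_sd = 0.3),
                            "HR", seed = 3)
  lag2 <- apply_sensor_model(tr, sensor_error_model("BH", rate = 4, lag = 2,
                                                    noise_sd = 0.3),
                             "HR", seed = 4)
  fr <- transpose_align(list(ref), resolution = 100)
  a <- resample_series(spline_fill(frame_channel(fr, "HR: VP")), 1000)
  fr2 <- transpose_align(list(lag2), resolution = 100, origin = 0)
  b <- resample_series(spline_fill(frame_channel(fr2, "HR: BH")), 1000)
  n <- min(length(a$t), length(b$t))
  cc <- cross_correlation(a$v[1:n], b$v[1:n], rate = 1)
  expect_equal(cc$best_lag, 2)
})

test_that("cohort generation is seeded, complete, and flags the degraded member", {
  co <- generate_cohort(n = 3, master_seed = 77)
  expect_length(co$participants, 3)
  expect_identical(co$manifest$degraded_id, "RP 1-2")
  expect_true(co$participants[["RP 1-2"]]$degraded)
  for (p in co$participants) {
    expect_length(p$streams, 9)  # all capability-table combinations
    plat <- vapply(p$streams, function(s) s$platform, character(1))
    par <- vapply(p$streams, function(s) s$parameter, character(1))
    expect_setequal(paste(plat, par),
                    paste(platform_capabilities()$platform,
                          platform_capabilities()$parameter))
  }
  # byte-identical regeneration from the same master seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(n = 1, master_seed = 42), d1)
  write_cohort(generate_cohort(n = 1, master_seed = 42), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 5e7),
                     readBin(file.path(d2, f), "raw", 5e7))
})

test_that("written cohorts read back into equivalent streams", {
  d <- withr::local_tempdir()
  co <- generate_cohort(n = 1, master_seed = 13, dir = d)
  back <- read_cohort(d)
  expect_length(back, 1)
  orig <- co$participants[[1]]$streams$VP.GSR
  got <- back[["RP 1-1"]][["VP.GSR"]]
  expect_equal(got$t, orig$t)
  expect_equal(got$v, orig$v, tolerance = 1e-9)  # CSV decimal round trip
})
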