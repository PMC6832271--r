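#' Ergometer session protocol
#'
#' The emulated study protocol: 5 min of rested sitting, 10 min of cycling
#' with the load stepped every 2 min through 35, 65, 100, 133 and 165 W,
#' then 5 min of seated cool-down; 1200 s in total.
#'
#' @return A data.frame with columns `name`, `start` (s), `duration` (s) and
#'   `load` (W).
#' @export
protocol_phases <- function() {
  data.frame(
    name = c("rest", paste0("step", 1:5), "cooldown"),
    start = c(0, 300, 420, 540, 660, 780, 900),
    duration = c(300, rep(120, 5), 300),
    load = c(0, 35, 65, 100, 133, 165, 0),
    stringsAsFactors = FALSE
  )
}

#' Population parameters of the truth simulator
#'
#' Ranges from which per-participant latent parameters are drawn, plus the
#' fixed cardiovascular dynamics and the injected HRV modulation. Defaults
#' are physiologically plausible for healthy adults on a stepped ergometer
#' protocol: resting heart rate 62-78 bpm, a load response of roughly
#' 0.38-0.52 bpm/W approached with a 30 s onset and 60 s recovery time
#' constant, tonic skin conductance baseline 2-10 microsiemens with a slow
#' load-driven drift and sparse phasic responses.
#'
#' @param ... Named overrides of any default.
#' @return A list of simulator parameters.
#' @export
truth_params <- function(...) {
  p <- list(
    dt = 0.25,                      # truth grid step, s (4 Hz)
    hr_rest_range = c(62, 78),      # bpm
    hr_gain_range = c(0.38, 0.52),  # bpm per W
    tau_on = 30, tau_off = 60,      # s, HR onset / recovery time constants
    hr_limits = c(45, 200),         # bpm
    lf_freq = 0.105, lf_amp_ms = 50,   # injected LF IBI modulation
    hf_freq = 0.30, hf_amp_ms = 20,    # injected HF (respiratory) modulation
    peak_jitter_ms = 2,
    gsr_base_range = c(2, 10),      # microsiemens
    gsr_drift_range = c(1.0, 3.0),  # microsiemens added at peak load
    gsr_drift_tau = 90,             # s
    gsr_event_rate = 1 / 45,        # phasic responses per s
    scr_amp_range = c(0.2, 0.8),    # microsiemens
    scr_rise = 1.5, scr_decay = 6   # s
  )
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Simulate ground-truth physiological trajectories
#'
#' Draws one participant's latent parameters and simulates heart rate as a
#' first-order exponential approach to a load-dependent target, inter-beat
#' intervals as 60000/HR plus sinusoidal LF and HF modulation of known
#' amplitude (so demodulation can be validated against ground truth), skin
#' conductance as tonic baseline + slow load-driven drift + phasic
#' exponential-decay responses at random event times, and an R-peak train
#' whose successive gaps follow the true IBI with small Gaussian jitter.
#' HR and IBI trajectories are exact reciprocals (times 60000) of each
#' other by construction.
#'
#' @param seed Integer seed; all randomness of this participant flows from
#'   it.
#' @param phases Protocol, see [protocol_phases()].
#' @param params Simulator parameters, see [truth_params()].
#' @return An object of class `truth_trajectories` with the 4 Hz truth
#'   grid (`t_s`), trajectories `hr` (bpm), `ibi` (ms), `gsr_tonic`,
#'   `gsr_phasic` (microsiemens), `peak_times_ms`, and the drawn `latent`
#'   parameters.
#' @export
simulate_truth <- function(seed, phases = protocol_phases(),
                           params = truth_params()) {
  stopifnot(is.data.frame(phases), nrow(phases) >= 1,
            all(phases$duration > 0), all(phases$load >= 0))
  set.seed(seed)
  dur <- max(phases$start + phases$duration)
  dt <- params$dt
  t_s <- seq(0, dur, by = dt)
  load <- numeric(length(t_s))
  for (i in seq_len(nrow(phases))) {
    sel <- t_s >= phases$start[i] & t_s < phases$start[i] + phases$duration[i]
    load[sel] <- phases$load[i]
  }
  load[length(load)] <- phases$load[nrow(phases)]

  lat <- list(
    hr_rest = stats::runif(1, params$hr_rest_range[1], params$hr_rest_range[2]),
    hr_gain = stats::runif(1, params$hr_gain_range[1], params$hr_gain_range[2]),
    gsr_base = stats::runif(1, params$gsr_base_range[1], params$gsr_base_range[2]),
    gsr_drift = stats::runif(1, params$gsr_drift_range[1], params$gsr_drift_range[2]),
    lf_phase = stats::runif(1, 0, 2 * pi),
    hf_phase = stats::runif(1, 0, 2 * pi)
  )

  # first-order load response with separate onset/recovery time constants
  target <- pmin(pmax(lat$hr_rest + lat$hr_gain * load, params$hr_limits[1]),
                 params$hr_limits[2])
  hr_dyn <- numeric(length(t_s))
  hr_dyn[1] <- lat$hr_rest
  for (i in 2:length(t_s)) {
    tau <- if (target[i] > hr_dyn[i - 1]) params$tau_on else params$tau_off
    hr_dyn[i] <- hr_dyn[i - 1] + dt * (target[i] - hr_dyn[i - 1]) / tau
  }
  ibi <- 60000 / hr_dyn +
    params$lf_amp_ms * sin(2 * pi * params$lf_freq * t_s + lat$lf_phase) +
    params$hf_amp_ms * sin(2 * pi * params$hf_freq * t_s + lat$hf_phase)
  # the modulation may not carry HR beyond the physiological limits
  ibi <- pmin(pmax(ibi, 60000 / params$hr_limits[2]),
              60000 / params$hr_limits[1])
  hr <- 60000 / ibi  # exact reciprocal consistency

  # R-peak train: successive gaps equal the local true IBI, plus jitter
  peaks <- numeric(0)
  tp <- 0
  while (tp < dur) {
    peaks <- c(peaks, tp)
    step_ms <- stats::approx(t_s, ibi, xout = tp, rule = 2)$y
    tp <- tp + step_ms / 1000
  }
  jit <- stats::rnorm(length(peaks), 0, params$peak_jitter_ms / 1000)
  peaks <- sort(peaks + c(0, jit[-1]))

  # skin conductance: tonic drift follows low-passed load, phasic responses
  lp_load <- numeric(length(t_s))
  for (i in 2:length(t_s))
    lp_load[i] <- lp_load[i - 1] +
      dt * (load[i] - lp_load[i - 1]) / params$gsr_drift_tau
  tonic <- lat$gsr_base + lat$gsr_drift * lp_load / max(max(load), 1)
  phasic <- numeric(length(t_s))
  te <- stats::rexp(1, params$gsr_event_rate)
  while (te < dur) {
    a <- stats::runif(1, params$scr_amp_range[1], params$scr_amp_range[2])
    rel <- t_s - te
    shape <- ifelse(rel > 0,
                    exp(-rel / params$scr_decay) - exp(-rel / params$scr_rise),
                    0)
    pk <- max(shape)
    if (pk > 0) phasic <- phasic + a * shape / pk
    te <- te + stats::rexp(1, params$gsr_event_rate)
  }

  structure(
    list(seed = seed, t_s = t_s, load = load, hr = hr, ibi = ibi,
         gsr_tonic = tonic, gsr_phasic = phasic,
         peak_times_ms = peaks * 1000, latent = lat, params = params,
         phases = phases),
    class = "truth_trajectories"
  )
}

#' @export
print.truth_trajectories <- function(x, ...) {
  cat(sprintf(
    "<truth_trajectories> seed %d: %.0f s, HR %.0f-%.0f bpm, %d beats\n",
    x$seed, max(x$t_s), min(x$hr), max(x$hr), length(x$peak_times_ms)))
  invisible(x)
}

#' Construct a sensor error model
#'
#' Describes how one platform degrades the truth for one parameter: the
#' sampling rate, a constant acquisition lag, a range-dependent offset
#' `a / value + b` (maximal in the low range, vanishing in the high range),
#' additive Gaussian noise, slow random-walk wander, and sample dropouts.
#' For skin conductance, `phasic_gain` scales the phasic component to model
#' platforms with different responsiveness to sweating; for ECG,
#' `ecg_amp`/`ecg_sigma_ms`/`ecg_noise_sd` shape the rendered Gaussian
#' R-wave pulse train.
#'
#' @param platform One of VP, BH, E4.
#' @param rate Sampling rate in Hz.
#' @param lag Acquisition lag in seconds (>= 0).
#' @param offset_a,offset_b Reciprocal and constant offset components.
#' @param noise_sd Additive noise SD in parameter units.
#' @param dropout_p Per-sample dropout probability in \[0, 0.2\].
#' @param wander_sd Random-walk increment SD per sqrt(s) (0 = none).
#' @param phasic_gain Gain on the phasic skin-conductance component.
#' @param ecg_amp R-wave amplitude in mV.
#' @param ecg_sigma_ms R-wave Gaussian width in ms.
#' @param ecg_noise_sd ECG baseline noise SD in mV.
#' @return An object of class `sensor_error_model`.
#' @export
sensor_error_model <- function(platform, rate, lag = 0, offset_a = 0,
                               offset_b = 0, noise_sd = 0, dropout_p = 0,
                               wander_sd = 0, phasic_gain = 1,
                               ecg_amp = 1, ecg_sigma_ms = 12,
                               ecg_noise_sd = 0.02) {
  platform <- match.arg(platform, .PLATFORMS)
  stopifnot(rate > 0, lag >= 0, dropout_p >= 0, dropout_p <= 0.2,
            noise_sd >= 0, wander_sd >= 0)
  structure(list(platform = platform, rate = rate, lag = lag,
                 offset_a = offset_a, offset_b = offset_b,
                 noise_sd = noise_sd, dropout_p = dropout_p,
                 wander_sd = wander_sd, phasic_gain = phasic_gain,
                 ecg_amp = ecg_amp, ecg_sigma_ms = ecg_sigma_ms,
                 ecg_noise_sd = ecg_noise_sd),
            class = "sensor_error_model")
}

#' Default per-platform sensor error models
#'
#' Models chosen to reproduce the error structure observed between the
#' reference recorder and the wearables: the reference (VP) is essentially
#' clean and leads in time; the chest belt (BH) lags 1 s and shows a
#' reciprocal heart-rate offset that is maximal at low rates; the wrist
#' band (E4) lags 2 s and is more responsive to sweating (larger phasic
#' skin-conductance gain). Sampling rates: VP GSR 25 Hz, E4 GSR 4 Hz, E4
#' IBI 64 Hz, ECG 250 Hz.
#'
#' @return Named list of [sensor_error_model()]s, keyed `"<platform>.<parameter>"`.
#' @export
default_sensor_models <- function() {
  list(
    VP.HR  = sensor_error_model("VP", rate = 25, noise_sd = 0.4,
                                dropout_p = 0.005),
    VP.IBI = sensor_error_model("VP", rate = 25, noise_sd = 4,
                                dropout_p = 0.005),
    VP.ECG = sensor_error_model("VP", rate = 250, dropout_p = 0.002,
                                ecg_amp = 1.0, ecg_noise_sd = 0.02),
    VP.GSR = sensor_error_model("VP", rate = 25, noise_sd = 0.05,
                                dropout_p = 0.005, phasic_gain = 1.0),
    BH.HR  = sensor_error_model("BH", rate = 1, lag = 1, offset_a = 300,
                                noise_sd = 0.8, dropout_p = 0.01),
    BH.IBI = sensor_error_model("BH", rate = 1, lag = 1, offset_b = -8,
                                noise_sd = 6, dropout_p = 0.01),
    BH.ECG = sensor_error_model("BH", rate = 250, lag = 1, dropout_p = 0.005,
                                ecg_amp = 0.9, ecg_noise_sd = 0.03),
    E4.IBI = sensor_error_model("E4", rate = 64, lag = 2, noise_sd = 5,
                                dropout_p = 0.01),
    E4.GSR = sensor_error_model("E4", rate = 4, lag = 2, offset_b = 0.3,
                                noise_sd = 0.08, dropout_p = 0.01,
                                phasic_gain = 1.6)
  )
}

#' Degrade a set of sensor models
#'
#' Emulates a participant with poor electrode contact: heavy dropout,
#' inflated noise, slow wander, and a weak, noisy ECG. Used for the
#' deliberately degraded cohort member.
#'
#' @param models Output of [default_sensor_models()].
#' @return The degraded model list.
#' @export
degrade_sensor_models <- function(models) {
  lapply(models, function(m) {
    m$dropout_p <- 0.2
    m$noise_sd <- m$noise_sd * 8
    m$wander_sd <- m$noise_sd * 0.25  # slow drift on top of the noise
    m$ecg_amp <- m$ecg_amp * 0.25
    m$ecg_noise_sd <- m$ecg_noise_sd * 6
    m$phasic_gain <- m$phasic_gain * 0.2
    m
  })
}

#' Render a sensor stream from ground truth
#'
#' Samples the requested truth trajectory at the model rate, shifts it by
#' the acquisition lag, applies the range-dependent offset, additive noise,
#' wander, and dropouts. ECG is rendered as a Gaussian R-wave pulse train
#' at the (lag-shifted) truth peak times.
#'
#' @param truth A [simulate_truth()] result.
#' @param model A [sensor_error_model()].
#' @param parameter One of HR, IBI, ECG, GSR; the (platform, parameter)
#'   combination must be allowed by [platform_capabilities()].
#' @param participant_id Label for the emitted stream.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as in [generate_cohort()], where all randomness flows from the
#'   participant seed).
#' @return A [sensor_stream()].
#' @export
apply_sensor_model <- function(truth, model, parameter,
                               participant_id = "RP 1-1", seed = NULL) {
  stopifnot(inherits(truth, "truth_trajectories"),
            inherits(model, "sensor_error_model"))
  parameter <- match.arg(parameter, c("HR", "IBI", "ECG", "GSR"))
  cap <- platform_capabilities()
  if (!any(cap$platform == model$platform & cap$parameter == parameter))
    stop("platform '", model$platform, "' does not measure '", parameter,
         "'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dur <- max(truth$t_s)
  dt <- 1 / model$rate
  t_s <- seq(0, dur, by = dt)

  if (parameter == "ECG") {
    v <- stats::rnorm(length(t_s), 0, model$ecg_noise_sd)
    pk <- truth$peak_times_ms / 1000 + model$lag
    sig <- model$ecg_sigma_ms / 1000
    half <- 4 * sig
    for (p in pk) {
      lo <- max(1L, ceiling((p - half) / dt) + 1L)
      hi <- min(length(t_s), floor((p + half) / dt) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      v[idx] <- v[idx] + model$ecg_amp * exp(-((t_s[idx] - p)^2) / (2 * sig^2))
    }
  } else {
    base <- switch(parameter,
                   HR = truth$hr,
                   IBI = truth$ibi,
                   GSR = truth$gsr_tonic + model$phasic_gain * truth$gsr_phasic)
    v <- stats::approx(truth$t_s, base, xout = pmax(t_s - model$lag, 0),
                       rule = 2)$y
    if (model$offset_a != 0 || model$offset_b != 0)
      v <- v + model$offset_a / v + model$offset_b
    if (model$noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, model$noise_sd)
    if (model$wander_sd > 0)
      v <- v + cumsum(stats::rnorm(length(v), 0, model$wander_sd * sqrt(dt)))
  }
  keep <- rep(TRUE, length(t_s))
  if (model$dropout_p > 0)
    keep <- stats::runif(length(t_s)) >= model$dropout_p
  if (!any(keep)) keep[1] <- TRUE
  sensor_stream(participant_id, model$platform, parameter,
                t = t_s[keep] * 1000, v = v[keep],
                nominal_rate = model$rate)
}

#' Generate a synthetic benchmark cohort
#'
#' Simulates `n` participants under the ergometer protocol and renders the
#' full set of per-platform streams allowed by [platform_capabilities()].
#' All randomness flows from `master_seed` (per-participant seeds are drawn
#' from it, and each participant's stream rendering continues that
#' participant's RNG stream in a fixed order). One cohort member — `RP 1-2`,
#' when n >= 2 — is deliberately degraded ([degrade_sensor_models()]) to
#' emulate a participant with failing electrode contact.
#'
#' @param n Number of participants (default 18).
#' @param master_seed Integer master seed.
#' @param dir Optional output directory; when given, each participant gets
#'   a subdirectory of CSV stream files (`t_ms,value`) plus a cohort-level
#'   `manifest.json` holding every ground-truth parameter.
#' @param phases,params Protocol and simulator parameters.
#' @param models Sensor error models (default [default_sensor_models()]).
#' @param degraded_index Which participant to degrade (default 2; 0 for
#'   none).
#' @return An object of class `benchmark_cohort`: list with `participants`
#'   (each holding `id`, `seed`, `degraded`, `truth`, `streams`) and
#'   `manifest`.
#' @export
generate_cohort <- function(n = 18, master_seed = 1, dir = NULL,
                            phases = protocol_phases(),
                            params = truth_params(),
                            models = default_sensor_models(),
                            degraded_index = if (n >= 2) 2L else 0L) {
  stopifnot(n >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- paste0("RP 1-", seq_len(n))
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    degraded <- i == degraded_index
    mods <- if (degraded) degrade_sensor_models(models) else models
    truth <- simulate_truth(seeds[i], phases = phases, params = params)
    streams <- list()
    for (key in names(mods)) {
      parameter <- sub("^.*\\.", "", key)
      streams[[key]] <- apply_sensor_model(truth, mods[[key]], parameter,
                                           participant_id = ids[i])
    }
    participants[[i]] <- list(id = ids[i], seed = seeds[i],
                              degraded = degraded, truth = truth,
                              streams = streams, models = mods)
  }
  names(participants) <- ids
  manifest <- list(
    master_seed = master_seed, n = n,
    degraded_id = if (degraded_index > 0) ids[degraded_index] else NA,
    protocol = phases,
    modulation = list(lf_freq = params$lf_freq, lf_amp_ms = params$lf_amp_ms,
                      hf_freq = params$hf_freq, hf_amp_ms = params$hf_amp_ms),
    lags_s = lapply(models, function(m) m$lag),
    participants = lapply(participants, function(p)
      list(id = p$id, seed = p$seed, degraded = p$degraded,
           latent = p$truth$latent))
  )
  cohort <- structure(list(participants = participants, manifest = manifest),
                      class = "benchmark_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.benchmark_cohort <- function(x, ...) {
  cat(sprintf("<benchmark_cohort> %d participants (degraded: %s)\n",
              x$manifest$n, x$manifest$degraded_id))
  invisible(x)
}

#' Write a cohort to disk in the ingest format
#'
#' One subdirectory per participant with `<platform>_<parameter>.csv`
#' files (`t_ms,value`), plus `manifest.json` with all ground-truth
#' parameters.
#'
#' @param cohort A `benchmark_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    pdir <- file.path(dir, gsub(" ", "_", p$id))
    dir.create(pdir, showWarnings = FALSE)
    for (key in names(p$streams)) {
      s <- p$streams[[key]]
      data.table::fwrite(
        data.frame(t_ms = s$t, value = s$v),
        file.path(pdir, paste0(gsub("\\.", "_", key), ".csv")))
    }
  }
  jsonlite::write_json(cohort$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return Named list (participant id -> list of [sensor_stream()]s).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (pd in list.dirs(dir, recursive = FALSE)) {
    id <- gsub("_", " ", basename(pd))
    files <- list.files(pd, pattern = "\\.csv$", full.names = TRUE)
    streams <- list()
    for (f in files) {
      key <- sub("\\.csv$", "", basename(f))
      parts <- strsplit(key, "_")[[1]]
      streams[[sub("_", ".", key)]] <-
        read_stream(f, participant_id = id, platform = parts[1],
                    parameter = parts[2])
    }
    out[[id]] <- streams
  }
  attr(out, "manifest") <- manifest
  out
}
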