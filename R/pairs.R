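#' Benchmark run configuration
#'
#' Collects every tunable of the pipeline with its default: grid
#' resolutions (100 ms general, 10 ms for ECG, 1 s for the metric battery),
#' the ±5 s moving-average window, the 0.05-0.5 Hz band filter for the
#' filtered skin-conductance variants, the 4 Hz IBI resampling rate, the
#' ±15 s cross-correlation lag range with differencing to stationarity, MIC
#' search parameters (alpha 0.6, clump factor 15), the ±0.1 band of the
#' nonlinearity classification, and the 60 s / 10 s local Fréchet window.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(...) {
  cfg <- list(
    resolution_ms = 100,
    ecg_resolution_ms = 10,
    analysis_resolution_ms = 1000,
    mvavg_half_window_s = 5,
    gsr_filter = list(hp = 0.05, lp = 0.5, order = 1),
    ibi_resample_rate_hz = 4,
    hrv_bands = c("VLF", "LF", "HF"),
    max_lag_s = 15,
    ccf_difference = TRUE,
    epsilon = 0.1,
    mic_alpha = 0.6,
    mic_c = 15,
    same_battery = c("r2", "ccf", "mic", "dtw", "frechet", "frechet_local"),
    cross_battery = c("r2", "mic"),
    cross_variant = "mvavg",
    frechet_window_s = 60,
    frechet_step_s = 10,
    min_overlap = 30,
    kmeans_k = 3,
    kmeans_nstart = 25
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = c("benchmark_config", "list"))
}

roster_table <- function(roster) {
  parsed <- lapply(roster, parse_channel)
  df <- data.frame(
    name = vapply(parsed, format, character(1)),
    parameter = vapply(parsed, function(x) x$parameter, character(1)),
    platform = vapply(parsed, function(x) x$platform, character(1)),
    derived = vapply(parsed, function(x) x$derived_from, character(1)),
    filtered = vapply(parsed, function(x) x$filtered, logical(1)),
    mvavg = vapply(parsed, function(x) x$mvavg, logical(1)),
    stringsAsFactors = FALSE
  )
  df$source <- vapply(parsed, channel_source_key, character(1))
  # deterministic roster order: parameter group, direct before derived,
  # platform, filtered, then moving-averaged variants
  df[order(match(df$parameter, .PARAMETERS),
           df$derived != "none",
           match(df$platform, .PLATFORMS),
           df$filtered, df$mvavg), , drop = FALSE]
}

#' Enumerate benchmark channel pairs
#'
#' Builds the pair roster of a run. Same-parameter pairs combine every two
#' channels of the same physiological parameter recorded (or derived) from
#' different sources, separately per variant level (raw and moving-averaged
#' channels are each paired with their own kind, filtered with filtered);
#' these receive the full battery (correlation plus similarity).
#' Cross-parameter pairs are all remaining unordered combinations of the
#' channels at the configured variant level (default: moving-averaged only)
#' and receive the correlation battery. Within a pair the reference
#' platform (VP) is listed first, so it acts as the independent series of
#' the cross-correlation.
#'
#' @param roster Character vector of channel names (see [channel_name()]).
#' @param cfg A [benchmark_config()].
#' @return A data.frame of class `pair_spec`: columns `a`, `b`, `label`,
#'   `group` (parameter group used for matrix blocks), `pair_type`
#'   (`same_parameter`/`cross_parameter`) and `battery` (`full`/
#'   `correlation`), in deterministic order.
#' @export
enumerate_pairs <- function(roster, cfg = benchmark_config()) {
  if (!length(roster)) stop("empty roster", call. = FALSE)
  df <- roster_table(roster)
  out <- list()
  # same-parameter pairs, per variant level
  for (par in unique(df$parameter)) {
    for (filt in c(FALSE, TRUE)) {
      for (mv in c(FALSE, TRUE)) {
        sub <- df[df$parameter == par & df$filtered == filt & df$mvavg == mv, ]
        if (nrow(sub) < 2) next
        for (i in seq_len(nrow(sub) - 1)) {
          for (j in (i + 1):nrow(sub)) {
            if (sub$source[i] == sub$source[j]) next
            out[[length(out) + 1L]] <- data.frame(
              a = sub$name[i], b = sub$name[j], group = par,
              pair_type = "same_parameter", battery = "full",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  # cross battery at the configured variant level
  level <- df[if (cfg$cross_variant == "mvavg") df$mvavg else !df$mvavg, ]
  seen <- if (length(out))
    do.call(rbind, out) else
    data.frame(a = character(), b = character())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  seen_keys <- key(seen$a, seen$b)
  if (nrow(level) >= 2) {
    for (i in seq_len(nrow(level) - 1)) {
      for (j in (i + 1):nrow(level)) {
        if (key(level$name[i], level$name[j]) %in% seen_keys) next
        out[[length(out) + 1L]] <- data.frame(
          a = level$name[i], b = level$name[j],
          group = paste(level$parameter[i], level$parameter[j], sep = "/"),
          pair_type = if (level$parameter[i] == level$parameter[j])
            "same_parameter" else "cross_parameter",
          battery = "correlation",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) stop("no pairs can be formed from this roster",
                         call. = FALSE)
  res <- do.call(rbind, out)
  res$label <- paste(res$a, res$b, sep = " vs ")
  rownames(res) <- NULL
  class(res) <- c("pair_spec", "data.frame")
  res
}
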