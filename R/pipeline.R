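#' Build the analysis channel set from raw streams
#'
#' Runs the full pre-processing chain of one participant: non-ECG streams
#' are aligned on the general grid (default 100 ms) and gap-filled by
#' spline; each ECG stream is aligned on its fine grid (default 10 ms),
#' gap-filled, and converted into derived channels (inter-beat intervals
#' via R-peak detection, then VLF/LF/HF complex-demodulation amplitudes).
#' Every channel is produced in a raw and a moving-averaged variant (and,
#' for skin conductance, band-filtered variants), then aggregated by cell
#' means onto the analysis grid (default 1 s) shared by the metric battery.
#' Channels that fail (flatline ECG, too few samples) are dropped with a
#' warning rather than aborting the participant.
#'
#' @param streams List of [sensor_stream()]s of one participant.
#' @param cfg A [benchmark_config()].
#' @return Named list of gap-free [parameter_series()] on the analysis
#'   grid, keyed by channel name.
#' @export
build_channels <- function(streams, cfg = benchmark_config()) {
  is_ecg <- vapply(streams, function(s) s$parameter == "ECG", logical(1))
  origin <- min(vapply(streams, function(s) min(s$t), numeric(1)))
  sources <- list()

  if (any(!is_ecg)) {
    frame <- transpose_align(streams[!is_ecg],
                             resolution = cfg$resolution_ms, origin = origin)
    for (ch in setdiff(names(frame), "t_ms")) {
      s <- tryCatch(spline_fill(frame_channel(frame, ch)),
                    error = function(e) {
                      warning("channel '", ch, "' dropped: ",
                              conditionMessage(e))
                      NULL
                    })
      if (!is.null(s)) sources[[ch]] <- s
    }
  }

  for (ecg in streams[is_ecg]) {
    derived <- tryCatch({
      fr <- transpose_align(list(ecg), resolution = cfg$ecg_resolution_ms,
                            origin = origin)
      es <- spline_fill(frame_channel(fr, setdiff(names(fr), "t_ms")))
      peaks <- detect_r_peaks(es)
      ibi <- ibi_from_peaks(peaks, platform = ecg$platform,
                            rate = cfg$ibi_resample_rate_hz)
      ds <- list(ibi)
      for (bn in cfg$hrv_bands)
        ds[[length(ds) + 1L]] <- complex_demodulation(ibi, bn)
      ds
    }, error = function(e) {
      warning("ECG channel of ", ecg$platform, " dropped: ",
              conditionMessage(e))
      NULL
    })
    for (s in derived) sources[[format(s$name)]] <- s
  }

  channels <- list()
  add <- function(s) {
    rs <- resample_series(s, cfg$analysis_resolution_ms)
    channels[[format(rs$name)]] <<- rs
  }
  for (s in sources) {
    add(s)
    add(moving_average(s, cfg$mvavg_half_window_s))
    if (s$name$parameter == "GSR") {
      fl <- tryCatch(
        butterworth_bandfilter(s, hp = cfg$gsr_filter$hp,
                               lp = cfg$gsr_filter$lp,
                               order = cfg$gsr_filter$order),
        error = function(e) {
          warning("filtered variant of '", format(s$name), "' dropped: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(fl)) {
        add(fl)
        add(moving_average(fl, cfg$mvavg_half_window_s))
      }
    }
  }
  channels
}

#' Aggregate a series onto a coarser regular grid
#'
#' Cell means over half-open cells `[t, t + res)` anchored at t = 0, the
#' same assignment rule as [transpose_align()].
#'
#' @param s A [parameter_series()].
#' @param res_ms Target resolution in ms.
#' @return A `parameter_series` on the coarser grid.
#' @export
resample_series <- function(s, res_ms) {
  res <- series_resolution(s)
  if (!is.na(res) && abs(res - res_ms) < 1e-9) return(s)
  cell <- floor(s$t / res_ms)
  ok <- !is.na(s$v)
  agg <- rowsum(s$v[ok], group = cell[ok])
  cnt <- rowsum(rep(1, sum(ok)), group = cell[ok])
  cells <- as.numeric(rownames(agg))
  full <- seq(min(cells), max(cells))
  v <- rep(NA_real_, length(full))
  v[match(cells, full)] <- agg[, 1] / cnt[, 1]
  out <- parameter_series(s$name, full * res_ms, v, scale = s$scale,
                          provenance = s$provenance)
  with_provenance(out, sprintf("resample(%gms)", res_ms))
}

slice_series <- function(s, t0, t1) {
  keep <- s$t >= t0 & s$t <= t1
  parameter_series(s$name, s$t[keep], s$v[keep], scale = s$scale,
                   provenance = s$provenance)
}

# longest contiguous stretch where both channels are observed
pair_overlap <- function(a, b) {
  t0 <- max(a$t[1], b$t[1])
  t1 <- min(a$t[length(a$t)], b$t[length(b$t)])
  if (t1 <= t0) return(NULL)
  a <- slice_series(a, t0, t1)
  b <- slice_series(b, t0, t1)
  if (length(a$t) != length(b$t)) return(NULL)
  ok <- !is.na(a$v) & !is.na(b$v)
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- (ends[best] - r$lengths[best] + 1L):ends[best]
  list(a = slice_series(a, a$t[idx[1]], a$t[idx[length(idx)]]),
       b = slice_series(b, b$t[idx[1]], b$t[idx[length(idx)]]))
}

#' Compute the metric battery for one participant
#'
#' For every enumerated pair, the correlation battery (R squared, maximal
#' information coefficient with the MIC minus R squared classification,
#' and — for same-parameter pairs — the lagged cross-correlation) is
#' computed on the original-scale overlap of the two channels, and the
#' similarity battery (DTW, global and moving-window Fréchet) on
#' unit-rescaled copies. Pairs whose channels are absent or overlap too
#' little yield missing cells; they never abort the run.
#'
#' @param x Either a list of [sensor_stream()]s (pre-processed via
#'   [build_channels()]) or an already-built named list of
#'   [parameter_series()].
#' @param pairs Optional [enumerate_pairs()] result; derived from the
#'   available channels when `NULL`.
#' @param cfg A [benchmark_config()].
#' @param participant Participant label (taken from the streams when
#'   available).
#' @return An object of class `participant_metrics`: `participant`,
#'   `pairs` (the pair spec), and `metrics`, a per-pair-label list with
#'   elements `r2`, `mic`, `score`, `class`, `ccf`, `dtw`,
#'   `frechet_global`, `frechet_local`, `n`, `status`.
#' @export
run_participant <- function(x, pairs = NULL, cfg = benchmark_config(),
                            participant = NULL) {
  if (length(x) && inherits(x[[1]], "sensor_stream")) {
    if (is.null(participant)) participant <- x[[1]]$participant_id
    channels <- build_channels(x, cfg)
  } else {
    channels <- x
    if (is.null(participant)) participant <- "participant"
  }
  if (is.null(pairs)) pairs <- enumerate_pairs(names(channels), cfg)

  metrics <- vector("list", nrow(pairs))
  names(metrics) <- pairs$label
  for (i in seq_len(nrow(pairs))) {
    cell <- list(r2 = NA_real_, mic = NA_real_, score = NA_real_,
                 class = NA_character_, ccf = NULL, dtw = NA_real_,
                 frechet_global = NA_real_, frechet_local = NULL,
                 n = 0L, status = "missing")
    a <- channels[[pairs$a[i]]]
    b <- channels[[pairs$b[i]]]
    if (!is.null(a) && !is.null(b)) {
      ov <- pair_overlap(a, b)
      if (!is.null(ov) && length(ov$a$t) >= cfg$min_overlap) {
        battery <- if (pairs$battery[i] == "full") cfg$same_battery else
          cfg$cross_battery
        cell <- tryCatch(
          compute_pair_metrics(ov$a, ov$b, battery, cfg),
          error = function(e) {
            warning("pair '", pairs$label[i], "' failed: ",
                    conditionMessage(e))
            cell$status <- "failed"
            cell
          })
      }
    }
    metrics[[i]] <- cell
  }
  structure(list(participant = participant, pairs = pairs, metrics = metrics),
            class = "participant_metrics")
}

compute_pair_metrics <- function(a, b, battery, cfg) {
  out <- list(r2 = NA_real_, mic = NA_real_, score = NA_real_,
              class = NA_character_, ccf = NULL, dtw = NA_real_,
              frechet_global = NA_real_, frechet_local = NULL,
              n = length(a$t), status = "ok")
  if ("r2" %in% battery)
    out$r2 <- suppressWarnings(linear_r2(a, b))
  if ("mic" %in% battery && length(a$t) >= 25)
    out$mic <- suppressWarnings(
      mic(a, b, alpha = cfg$mic_alpha, c = cfg$mic_c))
  if (is.finite(out$r2) && is.finite(out$mic)) {
    cls <- classify_association(out$mic, out$r2, cfg$epsilon)
    out$score <- cls$score
    out$class <- cls$value
  }
  if ("ccf" %in% battery)
    out$ccf <- cross_correlation(a, b, max_lag = cfg$max_lag_s,
                                 difference = cfg$ccf_difference,
                                 min_overlap = cfg$min_overlap)
  if (any(c("dtw", "frechet", "frechet_local") %in% battery)) {
    ra <- suppressWarnings(minmax_rescale(a))
    rb <- suppressWarnings(minmax_rescale(b))
    if ("dtw" %in% battery) out$dtw <- dtw_distance(ra, rb)
    if ("frechet" %in% battery) out$frechet_global <- frechet_global(ra, rb)
    if ("frechet_local" %in% battery) {
      span <- (length(ra$t) - 1) * series_resolution(ra) / 1000
      if (span >= cfg$frechet_window_s)
        out$frechet_local <- frechet_local(ra, rb,
                                           window = cfg$frechet_window_s,
                                           step = cfg$frechet_step_s)
    }
  }
  out
}

#' Run the benchmark over a cohort
#'
#' @param cohort A `benchmark_cohort` from [generate_cohort()], or a named
#'   list (participant id -> list of [sensor_stream()]s) as returned by
#'   [read_cohort()].
#' @param cfg A [benchmark_config()].
#' @param pairs Optional fixed pair spec shared by all participants.
#' @return Named list of [run_participant()] results, class `cohort_metrics`.
#' @export
run_cohort <- function(cohort, cfg = benchmark_config(), pairs = NULL) {
  plist <- if (inherits(cohort, "benchmark_cohort"))
    lapply(cohort$participants, function(p) p$streams) else cohort
  out <- lapply(names(plist), function(id)
    run_participant(plist[[id]], pairs = pairs, cfg = cfg, participant = id))
  names(out) <- names(plist)
  structure(out, class = c("cohort_metrics", "list"))
}

metric_accessor <- function(statistic) {
  switch(statistic,
    r2 = function(m) m$r2,
    mic = function(m) m$mic,
    score = function(m) m$score,
    dtw = function(m) m$dtw,
    frechet = function(m) m$frechet_global,
    best_lag = function(m) if (is.null(m$ccf)) NA_real_ else
      as.numeric(m$ccf$best_lag),
    best_r = function(m) if (is.null(m$ccf)) NA_real_ else m$ccf$best_r,
    stop("unknown statistic '", statistic, "'", call. = FALSE)
  )
}

#' Assemble a sorted participant-by-pair benchmark matrix
#'
#' Rows are channel pairs (grouped by parameter), columns participants.
#' Within each parameter group, rows are sorted by the cross-participant
#' mean of the chosen statistic — best first, i.e. descending for
#' correlation statistics and ascending for distances; columns are sorted
#' so the best-agreeing participant comes first. Row averages are carried
#' as a final pseudo-column and per-group column averages as group rows;
#' missing cells are excluded from every average, never imputed.
#'
#' @param results A `cohort_metrics` (or named list of
#'   [run_participant()] outputs).
#' @param statistic One of `"r2"`, `"mic"`, `"score"`, `"dtw"`,
#'   `"frechet"`, `"best_lag"`, `"best_r"`.
#' @param ascending Sort direction; defaults to ascending for the distance
#'   statistics, descending otherwise.
#' @return An object of class `benchmark_matrix` with fields `values`
#'   (sorted matrix), `row_groups`, `row_avgs`, `col_avgs`,
#'   `group_col_avgs`, `statistic`, `ascending`.
#' @export
assemble_matrix <- function(results, statistic = "r2", ascending = NULL) {
  if (!length(results)) stop("no participants", call. = FALSE)
  acc <- metric_accessor(statistic)
  if (is.null(ascending)) ascending <- statistic %in% c("dtw", "frechet")
  labels <- unique(unlist(lapply(results, function(r) r$pairs$label)))
  groups <- stats::setNames(
    unlist(lapply(results, function(r) r$pairs$group))[
      match(labels, unlist(lapply(results, function(r) r$pairs$label)))],
    labels)
  ids <- names(results)
  vals <- matrix(NA_real_, nrow = length(labels), ncol = length(ids),
                 dimnames = list(labels, ids))
  for (id in ids) {
    r <- results[[id]]
    for (lb in intersect(labels, names(r$metrics)))
      vals[lb, id] <- acc(r$metrics[[lb]])
  }
  row_means <- rowMeans(vals, na.rm = TRUE)
  col_means <- colMeans(vals, na.rm = TRUE)
  sgn <- if (ascending) 1 else -1
  # stable sort: group blocks keep enumeration order, rows by mean in-block
  grp <- factor(groups[labels], levels = unique(groups[labels]))
  row_ord <- order(as.integer(grp), sgn * ifelse(is.nan(row_means), sgn * Inf,
                                                 row_means))
  col_ord <- order(sgn * ifelse(is.nan(col_means), sgn * Inf, col_means))
  vals <- vals[row_ord, col_ord, drop = FALSE]
  groups <- groups[rownames(vals)]
  gca <- do.call(rbind, lapply(unique(groups), function(g) {
    colMeans(vals[groups == g, , drop = FALSE], na.rm = TRUE)
  }))
  rownames(gca) <- unique(groups)
  structure(
    list(values = vals, row_groups = groups,
         row_avgs = rowMeans(vals, na.rm = TRUE),
         col_avgs = colMeans(vals, na.rm = TRUE),
         group_col_avgs = gca,
         statistic = statistic, ascending = ascending),
    class = "benchmark_matrix")
}

#' @export
print.benchmark_matrix <- function(x, ...) {
  cat(sprintf("<benchmark_matrix> %s: %d pairs x %d participants (%s)\n",
              x$statistic, nrow(x$values), ncol(x$values),
              if (x$ascending) "ascending = more similar first"
              else "descending = best first"))
  print(round(x$values, 3))
  invisible(x)
}

#' Write a benchmark matrix as wide CSV
#'
#' One row per pair in sorted order with an `avg` column; a `<group> avg`
#' row closes each parameter group. The CSV is the single source of truth
#' for the heat-map renderer, byte-stable across runs.
#'
#' @param bm A `benchmark_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_benchmark_matrix <- function(bm, path) {
  rows <- list()
  for (g in unique(bm$row_groups)) {
    sel <- which(bm$row_groups == g)
    ids <- colnames(bm$values)
    for (i in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = rownames(bm$values)[i], group = g,
        as.list(stats::setNames(round(bm$values[i, ], 6), ids)),
        avg = round(bm$row_avgs[i], 6),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(g, "avg"), group = g,
      as.list(stats::setNames(round(bm$group_col_avgs[g, ], 6), ids)),
      avg = NA_real_, check.names = FALSE, stringsAsFactors = FALSE)
  }
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Write the tidy per-metric results of a cohort run
#'
#' Long CSV with columns participant, pair, pair_type, metric, lag, value;
#' cross-correlation coefficients contribute one row per lag. Deterministic
#' row order.
#'
#' @param results A `cohort_metrics`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(results, path) {
  rows <- list()
  for (id in names(results)) {
    r <- results[[id]]
    for (i in seq_len(nrow(r$pairs))) {
      lb <- r$pairs$label[i]
      m <- r$metrics[[lb]]
      emit <- function(metric, value, lag = NA_integer_) {
        rows[[length(rows) + 1L]] <<- data.frame(
          participant = id, pair = lb, pair_type = r$pairs$pair_type[i],
          metric = metric, lag = lag, value = value,
          stringsAsFactors = FALSE)
      }
      emit("r2", m$r2)
      emit("mic", m$mic)
      emit("score", m$score)
      emit("dtw", m$dtw)
      emit("frechet", m$frechet_global)
      if (!is.null(m$ccf)) {
        emit("best_lag", as.numeric(m$ccf$best_lag))
        for (j in seq_along(m$ccf$lags))
          emit("ccf_r", m$ccf$coefficients[j], m$ccf$lags[j])
      }
    }
  }
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Write the run manifest
#'
#' JSON record of the configuration and package version that produced a
#' run, sufficient to regenerate every output byte-identically together
#' with the cohort seed.
#'
#' @param cfg A [benchmark_config()].
#' @param path Output file.
#' @param extra Optional named list merged into the manifest (e.g. seeds).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(list(package = "wearbench",
                     version = as.character(utils::packageVersion("wearbench")),
                     config = unclass(cfg)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
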