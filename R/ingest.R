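#' Read a raw sensor stream from a delimited text file
#'
#' Accepts two dialects. The plain dialect has one sample per row with
#' columns `t_ms` and `value`. The packed dialect mirrors devices that store
#' one row per second with the sub-second samples packed into a delimited
#' payload string: columns `t_s`, `payload`, `rate_hz` (see
#' [unpack_packed_row()]).
#'
#' @param path Path to a CSV/TSV file.
#' @param participant_id,platform,parameter Stream identity (see
#'   [sensor_stream()]).
#' @param schema Optional named list mapping the roles `t`, `v` (plain
#'   dialect) or `t0`, `payload`, `rate` (packed dialect) to column names in
#'   the file. Defaults to the standard column names.
#' @param nominal_rate Optional sampling rate in Hz; inferred when `NULL`.
#' @return A [sensor_stream()] sorted by time.
#' @export
read_stream <- function(path, participant_id, platform, parameter,
                        schema = NULL, nominal_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE),
    error = function(e) stop("malformed file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0L) stop("empty stream file: ", path, call. = FALSE)
  cols <- names(dt)
  pick <- function(role, default) {
    nm <- if (!is.null(schema) && !is.null(schema[[role]])) schema[[role]] else default
    if (!nm %in% cols) return(NULL)
    nm
  }
  t_col <- pick("t", "t_ms"); v_col <- pick("v", "value")
  if (!is.null(t_col) && !is.null(v_col)) {
    t <- dt[[t_col]]; v <- dt[[v_col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(t))) |
                   !is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("malformed row at line ", bad[1] + 1L, " of ", path, call. = FALSE)
    t <- as.numeric(t); v <- as.numeric(v)
  } else {
    t0_col <- pick("t0", "t_s"); p_col <- pick("payload", "payload")
    r_col <- pick("rate", "rate_hz")
    if (is.null(t0_col) || is.null(p_col) || is.null(r_col))
      stop("cannot resolve columns in ", path,
           ": need (t_ms, value) or (t_s, payload, rate_hz)", call. = FALSE)
    rows <- lapply(seq_len(nrow(dt)), function(i) {
      unpack_packed_row(packed_row(dt[[t0_col]][i] * 1000, dt[[p_col]][i]),
                        rate = dt[[r_col]][i])
    })
    rows <- do.call(rbind, rows)
    t <- rows[, 1]; v <- rows[, 2]
  }
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  if (anyDuplicated(t)) {
    line <- which(duplicated(t))[1]
    stop("duplicate timestamp (t=", t[line], " ms) at sorted position ", line,
         " in ", path, call. = FALSE)
  }
  sensor_stream(participant_id, platform, parameter, t, v,
                nominal_rate = nominal_rate)
}

#' Construct a packed row
#'
#' One second's worth of sub-second samples stored as a delimited string, as
#' produced by loggers that write one database row per second regardless of
#' the channel sampling rate.
#'
#' @param t0 Row timestamp in ms (second resolution).
#' @param payload Delimited string of decimal values, e.g. `"1.0;2.0;3.0"`.
#' @param delim Payload delimiter (default `";"`, `","` also accepted).
#' @return An object of class `packed_row`.
#' @export
packed_row <- function(t0, payload, delim = ";") {
  structure(list(t0 = as.numeric(t0), payload = as.character(payload),
                 delim = delim),
            class = "packed_row")
}

#' Unpack a packed row into timestamped samples
#'
#' The k samples of a 1-second row are spread evenly over the second:
#' sample i (0-based) is stamped `t0 + i * 1000 / rate` ms, so that each
#' measurement carries its own sub-second timestamp.
#'
#' @param row A [packed_row()].
#' @param rate Sampling rate in Hz; the decoded sample count must equal
#'   `rate` for a 1-second row.
#' @return A two-column matrix `(t, v)`.
#' @export
unpack_packed_row <- function(row, rate) {
  stopifnot(inherits(row, "packed_row"))
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  parts <- strsplit(row$payload, paste0("[", row$delim, ",]"))[[1]]
  parts <- parts[nzchar(trimws(parts))]
  v <- suppressWarnings(as.numeric(parts))
  if (length(v) == 0L || anyNA(v))
    stop("cannot decode payload: '",
         substr(row$payload, 1, 40), "'", call. = FALSE)
  k <- length(v)
  if (k != round(rate))
    stop("payload has ", k, " samples but rate is ", rate, " Hz", call. = FALSE)
  t <- row$t0 + (seq_len(k) - 1L) * (1000 / rate)
  cbind(t = t, v = v)
}

#' Align sensor streams onto a common regular grid
#'
#' Transposes the vertical one-sample-per-row record layout into a wide
#' multichannel frame on a regular millisecond grid. Each raw sample is
#' assigned to the half-open grid cell `[t, t + resolution)` containing its
#' timestamp, with the grid anchored at the session start (the earliest
#' timestamp over all streams). Cells receiving no sample are missing; cells
#' receiving several samples hold their arithmetic mean.
#'
#' @param streams List of [sensor_stream()] objects from one participant.
#' @param resolution Grid step in ms, 10 or 100.
#' @param origin Session start in ms; defaults to the earliest timestamp
#'   across `streams` so that synchronized devices share the grid.
#' @return An `aligned_frame`: a data.frame with column `t_ms` plus one
#'   column per channel (named via the channel grammar), with attributes
#'   `resolution` and `participant`.
#' @export
transpose_align <- function(streams, resolution = 100, origin = NULL) {
  if (!length(streams)) stop("no streams supplied", call. = FALSE)
  if (!resolution %in% c(10, 100))
    stop("resolution must be 10 or 100 ms", call. = FALSE)
  pid <- unique(vapply(streams, function(s) s$participant_id, character(1)))
  if (length(pid) != 1L)
    stop("streams belong to different participants: ",
         paste(pid, collapse = ", "), call. = FALSE)
  spans <- t(vapply(streams, function(s) range(s$t), numeric(2)))
  if (nrow(spans) > 1L && max(spans[, 1]) > min(spans[, 2]))
    warning("streams have non-overlapping time spans; frame still produced")
  if (is.null(origin)) origin <- min(spans[, 1])
  t_max <- max(spans[, 2])
  n_cells <- floor((t_max - origin) / resolution) + 1L
  grid <- origin + (seq_len(n_cells) - 1L) * resolution
  out <- data.frame(t_ms = grid)
  for (s in streams) {
    ch <- format(channel_name(s$parameter, s$platform))
    cell <- floor((s$t - origin) / resolution) + 1L
    keep <- cell >= 1L & cell <= n_cells
    agg <- rowsum(s$v[keep], group = cell[keep])
    cnt <- rowsum(rep(1, sum(keep)), group = cell[keep])
    col <- rep(NA_real_, n_cells)
    col[as.integer(rownames(agg))] <- agg[, 1] / cnt[, 1]
    if (ch %in% names(out)) {
      # same (platform, parameter) split over several files: merge cells
      prev <- out[[ch]]
      col <- ifelse(is.na(prev), col, ifelse(is.na(col), prev, (prev + col) / 2))
    }
    out[[ch]] <- col
  }
  structure(out, resolution = resolution, participant = pid,
            class = c("aligned_frame", "data.frame"))
}

#' @export
print.aligned_frame <- function(x, ...) {
  cat(sprintf("<aligned_frame> %s: %d cells @ %g ms, %d channel(s)\n",
              attr(x, "participant"), nrow(x), attr(x, "resolution"),
              ncol(x) - 1L))
  for (ch in setdiff(names(x), "t_ms"))
    cat(sprintf("  %-28s missing %5.1f%%\n", ch, 100 * mean(is.na(x[[ch]]))))
  invisible(x)
}

#' Extract one channel of an aligned frame as a parameter series
#'
#' @param frame An `aligned_frame`.
#' @param channel Channel name (string or [channel_name()]).
#' @return A [parameter_series()] on the frame grid (missing cells as `NA`).
#' @export
frame_channel <- function(frame, channel) {
  nm <- if (inherits(channel, "channel_name")) format(channel) else channel
  if (!nm %in% names(frame))
    stop("channel '", nm, "' not in frame", call. = FALSE)
  parameter_series(parse_channel(nm), frame$t_ms, frame[[nm]])
}

#' Write an aligned frame to CSV
#' @param frame An `aligned_frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aligned_frame <- function(frame, path) {
  hdr <- sprintf("# resolution=%g participant=%s",
                 attr(frame, "resolution"), attr(frame, "participant"))
  writeLines(hdr, path)
  data.table::fwrite(as.data.frame(frame), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an aligned frame written by [write_aligned_frame()]
#' @param path CSV file.
#' @return An `aligned_frame`.
#' @export
read_aligned_frame <- function(path) {
  hdr <- readLines(path, n = 1L)
  res <- as.numeric(sub("^# resolution=([0-9.]+) .*$", "\\1", hdr))
  pid <- sub("^.* participant=", "", hdr)
  df <- as.data.frame(data.table::fread(path, skip = 1L, header = TRUE,
                                        check.names = FALSE))
  structure(df, resolution = res, participant = pid,
            class = c("aligned_frame", "data.frame"))
}
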