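#' Platform capability table
#'
#' Which physiological parameters each recording platform provides directly:
#' the laboratory reference recorder (VP) measures HR, IBI, ECG and GSR; the
#' chest-belt wearable (BH) measures HR, IBI and ECG; the wrist-band wearable
#' (E4) measures IBI and GSR.
#'
#' @return A data.frame with columns `platform` and `parameter`, one row per
#'   allowed direct measurement.
#' @export
platform_capabilities <- function() {
  data.frame(
    platform  = c("VP", "VP", "VP", "VP", "BH", "BH", "BH", "E4", "E4"),
    parameter = c("HR", "IBI", "ECG", "GSR", "HR", "IBI", "ECG", "IBI", "GSR"),
    stringsAsFactors = FALSE
  )
}

.PARAMETERS <- c("HR", "IBI", "ECG", "GSR", "VLF", "LF", "HF")
.PLATFORMS  <- c("VP", "BH", "E4")
.DERIVED_PARAMETERS <- c("IBI", "VLF", "LF", "HF")

#' Construct a channel name
#'
#' Channels are named after the measured (or derived) physiological
#' parameter, the platform that recorded the source signal, and flags for the
#' band-filtered and moving-averaged variants. The printed form follows the
#' study's naming convention, e.g. `"GSR: VP (mv. avg.)"` for the moving
#' averaged skin-conductance channel of the reference recorder, or
#' `"IBI: from ECG BH"` for the inter-beat interval derived from the
#' chest-belt ECG.
#'
#' @param parameter One of HR, IBI, ECG, GSR, VLF, LF, HF.
#' @param platform One of VP, BH, E4 (platform of the source signal).
#' @param derived_from `"none"` for direct measurements or `"ECG"` for
#'   channels derived from the ECG (IBI, VLF, LF, HF only).
#' @param filtered Logical; band-filtered variant (see
#'   [butterworth_bandfilter()]).
#' @param mvavg Logical; moving-averaged variant (see [moving_average()]).
#' @return An object of class `channel_name`.
#' @examples
#' channel_name("GSR", "VP", mvavg = TRUE)
#' channel_name("LF", "BH", derived_from = "ECG")
#' @export
channel_name <- function(parameter, platform,
                         derived_from = c("none", "ECG"),
                         filtered = FALSE, mvavg = FALSE) {
  parameter <- match.arg(parameter, .PARAMETERS)
  platform <- match.arg(platform, .PLATFORMS)
  derived_from <- match.arg(derived_from)
  if (parameter %in% c("VLF", "LF", "HF") && derived_from == "none") {
    # HRV band amplitudes only exist as ECG derivatives
    derived_from <- "ECG"
  }
  if (derived_from == "ECG") {
    if (!parameter %in% .DERIVED_PARAMETERS)
      stop("parameter '", parameter, "' cannot be derived from ECG", call. = FALSE)
    cap <- platform_capabilities()
    if (!any(cap$platform == platform & cap$parameter == "ECG"))
      stop("platform '", platform, "' does not record ECG", call. = FALSE)
  } else {
    cap <- platform_capabilities()
    if (!any(cap$platform == platform & cap$parameter == parameter))
      stop("platform '", platform, "' does not measure '", parameter, "'",
           call. = FALSE)
  }
  structure(
    list(parameter = parameter, platform = platform,
         derived_from = derived_from,
         filtered = isTRUE(filtered), mvavg = isTRUE(mvavg)),
    class = "channel_name"
  )
}

#' @export
format.channel_name <- function(x, ...) {
  base <- if (x$derived_from == "ECG") {
    paste0(x$parameter, ": from ", x$derived_from, " ", x$platform)
  } else {
    paste0(x$parameter, ": ", x$platform)
  }
  if (x$filtered) base <- paste0(base, " filt.")
  if (x$mvavg) base <- paste0(base, " (mv. avg.)")
  base
}

#' @export
print.channel_name <- function(x, ...) {
  cat("<channel> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.channel_name <- function(x, ...) format(x)

#' Parse a channel name string
#'
#' Inverse of [format()] on [channel_name()] objects. Accepts both the
#' colon-separated form used in printed matrices (`"GSR: VP (mv. avg.)"`)
#' and the colon-free form (`"GSR VP filt."`).
#'
#' @param x Character scalar.
#' @return A `channel_name` object.
#' @export
parse_channel <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- trimws(x)
  mvavg <- grepl("\\(mv\\. ?avg\\.?\\)\\s*$", s)
  s <- sub("\\s*\\(mv\\. ?avg\\.?\\)\\s*$", "", s)
  filtered <- grepl("\\bfilt\\.?\\s*$", s)
  s <- sub("\\s*filt\\.?\\s*$", "", s)
  s <- gsub(":", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  if (length(toks) == 4L && toks[2] == "from") {
    out <- channel_name(toks[1], toks[4], derived_from = toks[3],
                        filtered = filtered, mvavg = mvavg)
  } else if (length(toks) == 2L) {
    out <- channel_name(toks[1], toks[2],
                        filtered = filtered, mvavg = mvavg)
  } else {
    stop("cannot parse channel name: '", x, "'", call. = FALSE)
  }
  out
}

# variant-free identity of the underlying parameter source, used to group
# benchmark rows ("HR VP" and "HR VP (mv. avg.)" share a source)
channel_source_key <- function(ch) {
  paste(ch$parameter, ch$platform, ch$derived_from, sep = "|")
}

channel_parameter_group <- function(ch) ch$parameter
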