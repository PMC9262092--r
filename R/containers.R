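# Core containers: uniformly sampled signal streams, beat series, sessions.

#' Construct a uniformly sampled signal stream
#'
#' A `signal_stream` holds one or more channels sampled on a uniform grid,
#' anchored at a Unix start time (seconds since 1970-01-01 UTC). Sample `i`
#' (0-based) nominally occurs at `start_unix + i / fs`. Streams produced by
#' [merge_same_day()] may additionally carry *recorded gaps* — intervals
#' during which the device was off. Gaps shift the timestamps of all later
#' samples; no samples are fabricated inside a gap.
#'
#' @param start_unix Recording start, seconds since 1970-01-01 UTC.
#' @param fs Sampling frequency in Hz (> 0).
#' @param samples Numeric matrix (rows = time steps, columns = channels) or a
#'   vector for single-channel streams.
#' @param channel_names Character vector of channel names.
#' @param units Per-channel unit labels (recycled if length 1).
#' @param gaps Data frame with columns `start`, `end` (absolute Unix seconds)
#'   marking intervals with no recording; default none.
#' @return An object of class `signal_stream`.
#' @export
signal_stream <- function(start_unix, fs, samples,
                          channel_names = NULL, units = "",
                          gaps = NULL) {
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop("bad dialect: sampling frequency must be a single positive number",
         call. = FALSE)
  }
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_names)) {
    channel_names <- if (ncol(samples) == 1) "value" else paste0("ch", seq_len(ncol(samples)))
  }
  stopifnot(length(channel_names) == ncol(samples))
  colnames(samples) <- channel_names
  if (length(units) == 1) units <- rep(units, ncol(samples))
  if (is.null(gaps)) gaps <- data.frame(start = numeric(0), end = numeric(0))
  gaps <- gaps[order(gaps$start), , drop = FALSE]
  structure(
    list(start_unix = as.numeric(start_unix), fs = as.numeric(fs),
         samples = samples, channel_names = channel_names,
         units = units, gaps = gaps),
    class = "signal_stream"
  )
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream> %d sample(s) x %d channel(s) @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$fs))
  cat(sprintf("  start: %s UTC (%.3f)\n",
              format(as.POSIXct(x$start_unix, origin = "1970-01-01", tz = "UTC")),
              x$start_unix))
  cat(sprintf("  channels: %s\n",
              paste(x$channel_names, paste0("[", x$units, "]"), collapse = ", ")))
  if (nrow(x$gaps) > 0) cat(sprintf("  recorded gaps: %d\n", nrow(x$gaps)))
  invisible(x)
}

#' Number of samples in a stream
#' @param stream A [signal_stream()].
#' @return Integer sample count.
#' @export
n_samples <- function(stream) nrow(stream$samples)

#' Absolute sample timestamps of a stream
#'
#' Timestamps account for recorded gaps: samples after a gap are shifted by
#' the gap's duration.
#'
#' @param stream A [signal_stream()].
#' @return Numeric vector of Unix times, one per sample.
#' @export
stream_times <- function(stream) {
  n <- n_samples(stream)
  if (n == 0) return(numeric(0))
  t <- stream$start_unix + (seq_len(n) - 1) / stream$fs
  if (nrow(stream$gaps) > 0) {
    for (g in seq_len(nrow(stream$gaps))) {
      gs <- stream$gaps$start[g]; ge <- stream$gaps$end[g]
      shift <- t >= gs - 1e-9
      t[shift] <- t[shift] + (ge - gs)
    }
  }
  t
}

#' Recorded duration of a stream in seconds
#'
#' Span from the first sample to one sampling period past the last sample,
#' excluding recorded gaps (so it is the duration of actual data).
#'
#' @param stream A [signal_stream()].
#' @return Duration in seconds.
#' @export
stream_duration <- function(stream) n_samples(stream) / stream$fs

#' End time of a stream (absolute Unix seconds)
#' @param stream A [signal_stream()].
#' @return Unix time just past the last sample (start for empty streams).
#' @export
stream_end <- function(stream) {
  n <- n_samples(stream)
  if (n == 0) return(stream$start_unix)
  stream_times(stream)[n] + 1 / stream$fs
}

# Split a gapped stream into contiguous gap-free segments.
stream_segments <- function(stream) {
  if (nrow(stream$gaps) == 0) return(list(stream))
  t <- stream_times(stream)
  breaks <- which(diff(t) > 1.5 / stream$fs)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(t))
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    signal_stream(t[starts[i]], stream$fs,
                  stream$samples[idx, , drop = FALSE],
                  stream$channel_names, stream$units)
  })
}

# Slice a stream to the absolute time window [from, to), rebasing start_unix.
stream_window <- function(stream, from, to) {
  t <- stream_times(stream)
  keep <- which(t >= from - 1e-9 & t < to - 1e-9)
  if (length(keep) == 0) {
    return(signal_stream(from, stream$fs,
                         stream$samples[0, , drop = FALSE],
                         stream$channel_names, stream$units))
  }
  gaps <- stream$gaps[stream$gaps$end > from & stream$gaps$start < to, , drop = FALSE]
  if (nrow(gaps) > 0) {
    gaps$start <- pmax(gaps$start, from)
    gaps$end <- pmin(gaps$end, to)
  }
  signal_stream(t[keep[1]], stream$fs,
                stream$samples[keep, , drop = FALSE],
                stream$channel_names, stream$units, gaps = gaps)
}

#' Construct an inter-beat-interval (RR) series
#'
#' Beats are located by their offset in seconds since `start_unix`; each
#' carries the duration of the interval ending at that beat. Device exports
#' may contain gaps where noisy beats were discarded, so consecutive offsets
#' may differ by more than the recorded interval.
#'
#' @param start_unix Recording start, Unix seconds UTC.
#' @param beat_offsets Seconds since `start_unix` of each detected beat;
#'   strictly increasing.
#' @param intervals Inter-beat duration in seconds, one per beat (> 0).
#' @param accepted Logical acceptance flags (default all `TRUE`); set by
#'   [filter_rr()].
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(start_unix, beat_offsets, intervals,
                      accepted = rep(TRUE, length(beat_offsets))) {
  beat_offsets <- as.numeric(beat_offsets)
  intervals <- as.numeric(intervals)
  if (length(beat_offsets) != length(intervals)) {
    stop("bad dialect: offsets and intervals differ in length", call. = FALSE)
  }
  if (length(beat_offsets) > 1 && any(diff(beat_offsets) <= 0)) {
    stop("non-monotone beats", call. = FALSE)
  }
  if (any(intervals <= 0)) stop("bad interval", call. = FALSE)
  structure(
    list(start_unix = as.numeric(start_unix), beat_offsets = beat_offsets,
         intervals = intervals, accepted = as.logical(accepted)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beat(s), %d accepted\n",
              length(x$beat_offsets), sum(x$accepted)))
  invisible(x)
}

#' Number of beats in an RR series
#' @param series An [rr_series()].
#' @return Integer beat count.
#' @export
n_beats <- function(series) length(series$beat_offsets)

#' Construct an E4 recording session
#'
#' Bundles the streams, beat series and event tags of one recording (or of
#' several same-day recordings merged with [merge_same_day()]).
#'
#' @param eda,bvp,hr,temp,acc Optional [signal_stream()]s.
#' @param ibi Optional [rr_series()].
#' @param tags Optional numeric vector of event-marker Unix times.
#' @param source_names Character vector of originating archive names.
#' @param tz_offset Display-timezone offset in minutes relative to UTC.
#' @return An object of class `e4_session`.
#' @export
e4_session <- function(eda = NULL, bvp = NULL, hr = NULL, temp = NULL,
                       acc = NULL, ibi = NULL, tags = NULL,
                       source_names = "<memory>", tz_offset = 0) {
  stopifnot(length(source_names) >= 1)
  structure(
    list(eda = eda, bvp = bvp, hr = hr, temp = temp, acc = acc,
         ibi = ibi, tags = tags,
         source_names = source_names, tz_offset = as.numeric(tz_offset)),
    class = "e4_session"
  )
}

session_stream_names <- function(session) {
  present <- vapply(c("eda", "bvp", "hr", "temp", "acc"),
                    function(nm) !is.null(session[[nm]]), logical(1))
  names(present)[present]
}

#' Session start and end (absolute Unix seconds)
#'
#' The span from the earliest stream/beat start to the latest stream/beat end.
#'
#' @param session An [e4_session()].
#' @return Numeric vector `c(start, end)`.
#' @export
session_span <- function(session) {
  starts <- ends <- numeric(0)
  for (nm in session_stream_names(session)) {
    s <- session[[nm]]
    if (n_samples(s) > 0) {
      starts <- c(starts, s$start_unix)
      ends <- c(ends, stream_end(s))
    }
  }
  if (!is.null(session$ibi) && n_beats(session$ibi) > 0) {
    starts <- c(starts, session$ibi$start_unix)
    ends <- c(ends, session$ibi$start_unix + max(session$ibi$beat_offsets))
  }
  if (length(starts) == 0) stop("no analyzable data", call. = FALSE)
  c(min(starts), max(ends))
}

#' @export
print.e4_session <- function(x, ...) {
  cat("<e4_session>", paste(x$source_names, collapse = " + "), "\n")
  for (nm in session_stream_names(x)) {
    s <- x[[nm]]
    cat(sprintf("  %-4s %7d samples @ %5.4g Hz\n", toupper(nm), n_samples(s), s$fs))
  }
  if (!is.null(x$ibi)) cat(sprintf("  IBI  %7d beats\n", n_beats(x$ibi)))
  if (!is.null(x$tags)) cat(sprintf("  tags %7d\n", length(x$tags)))
  invisible(x)
}

#' Format a Unix time in the session display timezone
#' @param unix_time Unix seconds.
#' @param tz_offset Display offset in minutes.
#' @return Character timestamp `YYYY-MM-DD HH:MM:SS`.
#' @export
format_session_time <- function(unix_time, tz_offset = 0) {
  format(as.POSIXct(unix_time + tz_offset * 60, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%d %H:%M:%S")
}

# Calendar day ("YYYY-MM-DD") of a Unix time in the display timezone.
session_day <- function(unix_time, tz_offset = 0) {
  format(as.POSIXct(unix_time + tz_offset * 60, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%d")
}
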