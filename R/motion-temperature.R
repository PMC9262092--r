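# Movement magnitude, high-movement flagging, and stream summaries.

#' Movement analysis configuration
#'
#' @param counts_per_g Raw accelerometer counts per 1 g. The E4 reports
#'   signed counts spanning -2g..2g at 64 counts/g.
#' @param flag_threshold Mean acceleration (g) above which a period is
#'   flagged as high movement. The default 1.07 flags periods with over 7%
#'   of mean acceleration above rest, since movement is a common artifact
#'   source.
#' @return A list of class `movement_config`.
#' @export
movement_config <- function(counts_per_g = 64, flag_threshold = 1.07) {
  stopifnot(counts_per_g > 0, flag_threshold > 0)
  structure(list(counts_per_g = counts_per_g, flag_threshold = flag_threshold),
            class = "movement_config")
}

#' Mean acceleration magnitude in g
#'
#' Computes `sqrt(x^2 + y^2 + z^2) / counts_per_g` per sample, converting
#' the tri-axial raw counts to the magnitude of acceleration in gravity
#' units. A device at rest reads 1 g.
#'
#' @param acc Three-channel raw-count [signal_stream()].
#' @param cfg A [movement_config()].
#' @return Single-channel [signal_stream()] in g, same start and rate.
#' @export
acc_mean_magnitude <- function(acc, cfg = movement_config()) {
  if (ncol(acc$samples) != 3) {
    stop("expected 3 axes, got ", ncol(acc$samples), call. = FALSE)
  }
  mag <- sqrt(rowSums(acc$samples^2)) / cfg$counts_per_g
  signal_stream(acc$start_unix, acc$fs, mag, "magnitude", "g", gaps = acc$gaps)
}

#' Flag high-movement periods
#'
#' Applies a centered rolling mean of `window` seconds to the magnitude
#' stream and returns the maximal intervals where it exceeds
#' `cfg$flag_threshold`.
#'
#' @param mag Magnitude [signal_stream()] in g from [acc_mean_magnitude()].
#' @param cfg A [movement_config()].
#' @param window Rolling-mean window in seconds.
#' @return Data frame of disjoint, sorted intervals with columns `start`,
#'   `end` (seconds relative to the stream start) and `duration`.
#' @export
flag_high_movement <- function(mag, cfg = movement_config(), window = 1) {
  v <- mag$samples[, 1]
  n <- length(v)
  empty <- data.frame(start = numeric(0), end = numeric(0), duration = numeric(0))
  if (n == 0) return(empty)
  k <- max(1L, round(window * mag$fs))
  sm <- if (k > 1 && n >= k) {
    zoo::rollmean(v, k, fill = NA, align = "center")
  } else v
  above <- !is.na(sm) & sm > cfg$flag_threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  t0 <- stream_times(mag)[1]
  tt <- stream_times(mag) - t0
  data.frame(start = tt[starts[sel]],
             end = tt[ends[sel]] + 1 / mag$fs,
             duration = tt[ends[sel]] + 1 / mag$fs - tt[starts[sel]])
}

#' Summary statistics of a stream
#'
#' @param stream A single-channel [signal_stream()].
#' @param mask Optional logical validity mask (one element per sample);
#'   masked-out samples are excluded.
#' @return A list with `mean`, `min`, `max`, `median`, `n`.
#' @export
summarize_stream <- function(stream, mask = NULL) {
  v <- stream$samples[, 1]
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(v))
    v <- v[mask]
  }
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no analyzable data", call. = FALSE)
  list(mean = mean(v), min = min(v), max = max(v),
       median = stats::median(v), n = length(v))
}
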