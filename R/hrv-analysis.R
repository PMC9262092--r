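# Inter-beat-interval plausibility filtering and heart-rate variability.
#
# Wrist PPG beat series are artifact-prone; the filter enforces standard
# physiological bounds: resting heart rate stays within 40-180 bpm, so an
# RR interval at the 40 bpm bound is at most 60/40 = 1.5 s, and the ratio of
# the longest to the shortest RR interval within a 10-s segment stays below
# 1.1 (heart rate rarely changes by more than 10% at rest). Allowing for a
# single missed beat doubles both bounds: max RR 3 s, max ratio 2.2.

#' RR-interval filter configuration
#'
#' @param bpm_min,bpm_max Plausible resting heart-rate range in beats per
#'   minute. The corresponding RR bounds are `60/bpm_max` (shortest) and
#'   `60/bpm_min` (longest).
#' @param segment_len Window length in seconds for the max/min ratio rule.
#' @param ratio_max Maximum allowed max/min RR ratio within a window.
#' @param missed_beat_factor Allowance for a single missed beat: the hard
#'   upper RR bound becomes `missed_beat_factor * 60/bpm_min` and the
#'   windowed ratio bound `missed_beat_factor * ratio_max`. Set to 1 to
#'   disable the allowance.
#' @return A list of class `rr_filter_config`.
#' @export
rr_filter_config <- function(bpm_min = 40, bpm_max = 180, segment_len = 10,
                             ratio_max = 1.1, missed_beat_factor = 2) {
  stopifnot(bpm_min > 0, bpm_min < bpm_max, segment_len > 0,
            ratio_max >= 1, missed_beat_factor >= 1)
  structure(list(bpm_min = bpm_min, bpm_max = bpm_max,
                 segment_len = segment_len, ratio_max = ratio_max,
                 missed_beat_factor = missed_beat_factor),
            class = "rr_filter_config")
}

#' Longest plausible RR interval under the filter rules
#'
#' @param cfg An [rr_filter_config()].
#' @param allow_missed Include the single-missed-beat allowance?
#' @return Bound in seconds: `60/bpm_min`, times `missed_beat_factor` when
#'   the allowance applies (1.5 s at 40 bpm; 3 s allowing one missed beat).
#' @export
rr_max_interval <- function(cfg = rr_filter_config(), allow_missed = FALSE) {
  b <- 60 / cfg$bpm_min
  if (allow_missed) b * cfg$missed_beat_factor else b
}

#' Windowed max/min RR ratio bound under the filter rules
#'
#' @param cfg An [rr_filter_config()].
#' @param allow_missed Include the single-missed-beat allowance?
#' @return The ratio bound (1.1 at rest; 2.2 allowing one missed beat).
#' @export
rr_ratio_bound <- function(cfg = rr_filter_config(), allow_missed = FALSE) {
  if (allow_missed) cfg$ratio_max * cfg$missed_beat_factor else cfg$ratio_max
}

#' Convert beats per minute to beat frequency in Hz
#'
#' @param bpm Beats per minute.
#' @return Frequency in Hz (`bpm/60`); 40 bpm corresponds to 0.67 Hz.
#' @export
bpm_to_hz <- function(bpm) bpm / 60

#' Filter an RR series with physiological plausibility rules
#'
#' A beat is rejected when (in this order):
#' 1. its interval is shorter than `60/bpm_max` seconds, or longer than the
#'    missed-beat-allowed maximum `missed_beat_factor * 60/bpm_min`;
#' 2. within any `segment_len`-second window ending at an accepted beat, the
#'    max/min ratio of accepted intervals exceeds
#'    `missed_beat_factor * ratio_max` — the later beat of the offending
#'    pair is rejected first and the window re-evaluated;
#' 3. its interval exceeds `60/bpm_min` (so cannot be a plausible single
#'    beat) while its within-window ratio exceeds `ratio_max` — i.e. a long
#'    interval out of keeping with its neighbours, with no missed-beat
#'    excuse accepted.
#'
#' The filter is idempotent: running it on its own output changes nothing.
#'
#' @param series An [rr_series()].
#' @param cfg An [rr_filter_config()].
#' @return A list of class `rr_filter_result`: `series` (with `accepted`
#'   flags set), `n_original`, `n_accepted`.
#' @export
filter_rr <- function(series, cfg = rr_filter_config()) {
  n <- n_beats(series)
  if (n == 0) {
    return(structure(list(series = series, n_original = 0L, n_accepted = 0L),
                     class = "rr_filter_result"))
  }
  int <- series$intervals
  off <- series$beat_offsets
  acc <- series$accepted
  min_rr <- 60 / cfg$bpm_max
  max_rr <- 60 / cfg$bpm_min
  max_rr_allowed <- cfg$missed_beat_factor * max_rr
  ratio_hi <- cfg$ratio_max * cfg$missed_beat_factor

  # rule 1: hard interval bounds
  acc <- acc & int >= min_rr & int <= max_rr_allowed

  window_ratio <- function(i, acc) {
    in_win <- acc & off >= off[i] - cfg$segment_len & off <= off[i]
    w <- int[in_win]
    if (length(w) < 2) return(1)
    max(w) / min(w)
  }

  # rule 2: windowed ratio with missed-beat allowance, iterative rejection
  repeat {
    changed <- FALSE
    for (i in which(acc)) {
      in_win <- which(acc & off >= off[i] - cfg$segment_len & off <= off[i])
      if (length(in_win) < 2) next
      w <- int[in_win]
      if (max(w) / min(w) > ratio_hi) {
        pair <- c(in_win[which.max(w)], in_win[which.min(w)])
        acc[max(pair)] <- FALSE # reject the later beat of the offending pair
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }

  # rule 3: implausibly long single interval without missed-beat excuse
  repeat {
    changed <- FALSE
    for (i in which(acc)) {
      if (int[i] > max_rr && window_ratio(i, acc) > cfg$ratio_max) {
        acc[i] <- FALSE
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }

  out <- series
  out$accepted <- acc
  structure(list(series = out, n_original = n, n_accepted = sum(acc)),
            class = "rr_filter_result")
}

#' @export
print.rr_filter_result <- function(x, ...) {
  cat(sprintf("<rr_filter_result> %d / %d beats accepted (%.1f%%)\n",
              x$n_accepted, x$n_original,
              if (x$n_original > 0) 100 * x$n_accepted / x$n_original else NA))
  invisible(x)
}

accepted_intervals <- function(series) series$intervals[series$accepted]

#' Interpolated instantaneous heart-rate series
#'
#' Builds the non-interpolated heart-rate series (60/interval bpm at each
#' accepted beat time) and linearly interpolates it onto a uniform grid
#' spanning the first to the last accepted beat, for time-series and
#' spectral analysis.
#'
#' @param series An [rr_series()] (typically after [filter_rr()]).
#' @param fs Grid frequency in Hz.
#' @return A single-channel [signal_stream()] in bpm.
#' @export
rr_to_hr_series <- function(series, fs = 4) {
  keep <- series$accepted
  if (sum(keep) < 2) stop("insufficient beats", call. = FALSE)
  t_beat <- series$beat_offsets[keep]
  hr <- 60 / series$intervals[keep]
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / fs)
  y <- stats::approx(t_beat, hr, xout = grid, rule = 2)$y
  signal_stream(series$start_unix + t_beat[1], fs, y, "hr", "bpm")
}

#' Time-domain HRV measures
#'
#' Standard definitions over accepted beats: mean heart rate `60/mean(RR)`;
#' SDNN, the standard deviation of RR intervals; RMSSD, the root mean square
#' of successive RR differences; pNN50, the percentage of successive
#' differences exceeding 50 ms.
#'
#' @param series An [rr_series()] (accepted beats only are used).
#' @return A list of class `hrv_time_domain`: `mean_hr` (bpm), `sdnn` (ms),
#'   `rmssd` (ms), `pnn50` (percent).
#' @export
hrv_time_domain <- function(series) {
  rr <- accepted_intervals(series)
  if (length(rr) < 2) stop("insufficient beats", call. = FALSE)
  d <- diff(rr) * 1000 # ms
  structure(list(
    mean_hr = 60 / mean(rr),
    sdnn = stats::sd(rr) * 1000,
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  ), class = "hrv_time_domain")
}

# Welch power spectral density estimate (one-sided, Hann window).
# Scaled so that sum(psd) * df equals the variance of x (Parseval).
welch_psd <- function(x, fs, seg_len_s = 120, overlap = 0.5) {
  n <- length(x)
  L <- min(n, round(seg_len_s * fs))
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  k <- seq_len(L) - 1
  w <- 0.5 - 0.5 * cos(2 * pi * k / (L - 1))
  U <- sum(w^2)
  nfreq <- floor(L / 2) + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * U)
    half <- sp[seq_len(nfreq)]
    # fold in the negative frequencies (all but DC and Nyquist-if-even)
    if (L %% 2 == 0) {
      half[2:(nfreq - 1)] <- 2 * half[2:(nfreq - 1)]
    } else if (nfreq > 1) {
      half[2:nfreq] <- 2 * half[2:nfreq]
    }
    acc <- acc + half
  }
  psd <- acc / length(starts)
  list(freq = (seq_len(nfreq) - 1) * fs / L, psd = psd, df = fs / L)
}

#' Frequency-domain HRV measures
#'
#' Converts the interpolated heart-rate series to an RR tachogram in
#' milliseconds, removes the mean, estimates the power spectral density by
#' Welch's method (Hann window, 120-s segments, 50% overlap) and integrates
#' it over the conventional bands: VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz,
#' HF 0.15-0.4 Hz.
#'
#' @param hr_series Uniform heart-rate [signal_stream()] in bpm, from
#'   [rr_to_hr_series()].
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @param min_duration Minimum series duration in seconds.
#' @return A list of class `hrv_frequency_domain`: `vlf_power`, `lf_power`,
#'   `hf_power` (ms^2), `lf_hf_ratio`, `interpolation_fs`, `total_power`.
#' @export
hrv_frequency_domain <- function(hr_series,
                                 bands = list(vlf = c(0.003, 0.04),
                                              lf = c(0.04, 0.15),
                                              hf = c(0.15, 0.4)),
                                 min_duration = 120) {
  n <- n_samples(hr_series)
  if (n / hr_series$fs < min_duration) {
    stop("insufficient duration: need at least ", min_duration, " s",
         call. = FALSE)
  }
  rr_ms <- 60000 / hr_series$samples[, 1]
  x <- rr_ms - mean(rr_ms)
  est <- welch_psd(x, hr_series$fs, seg_len_s = min(120, n / hr_series$fs))
  band_power <- function(b) {
    sel <- est$freq >= b[1] & est$freq < b[2]
    sum(est$psd[sel]) * est$df
  }
  vlf <- band_power(bands$vlf)
  lf <- band_power(bands$lf)
  hf <- band_power(bands$hf)
  structure(list(
    vlf_power = vlf, lf_power = lf, hf_power = hf,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
    interpolation_fs = hr_series$fs,
    total_power = sum(est$psd) * est$df
  ), class = "hrv_frequency_domain")
}
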