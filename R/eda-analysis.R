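# Electrodermal activity: preprocessing, epoch artifact screening, validity
# rules, skin-conductance-response (SCR) peak detection and features.

#' EDA analysis configuration
#'
#' @param target_fs Output sampling rate of preprocessing in Hz. The native
#'   EDA rate is 4 Hz; the signal is upsampled to 8 Hz before filtering.
#' @param filter_cutoff Low-pass cutoff in Hz. SCR energy lives below ~1 Hz.
#' @param filter_taps Number of FIR taps (odd, linear phase).
#' @param epoch_len Artifact-screening epoch length in seconds.
#' @param peak_amplitude_threshold Minimum SCR amplitude in microSiemens; a
#'   rise smaller than this is not counted as a response.
#' @param classifier_mode `"binary"` (artifact / clean) or `"ternary"`
#'   (artifact / unclear / clean).
#' @param valid_min,valid_max Device validity range in microSiemens; samples
#'   outside `[valid_min, valid_max]` are discarded from peaks and summaries.
#' @return A list of class `eda_config`.
#' @export
eda_config <- function(target_fs = 8, filter_cutoff = 1.0, filter_taps = 33,
                       epoch_len = 5, peak_amplitude_threshold = 0.005,
                       classifier_mode = c("binary", "ternary"),
                       valid_min = 0.01, valid_max = 100) {
  classifier_mode <- match.arg(classifier_mode)
  stopifnot(target_fs > 0, epoch_len > 0, peak_amplitude_threshold > 0,
            valid_min >= 0, valid_min < valid_max, filter_taps >= 3)
  structure(list(target_fs = target_fs, filter_cutoff = filter_cutoff,
                 filter_taps = filter_taps, epoch_len = epoch_len,
                 peak_amplitude_threshold = peak_amplitude_threshold,
                 classifier_mode = classifier_mode,
                 valid_min = valid_min, valid_max = valid_max),
            class = "eda_config")
}

#' Preprocess an EDA stream
#'
#' Upsamples the signal to `cfg$target_fs` (linear interpolation, which is
#' monotone and cannot fabricate peaks) and applies a zero-phase FIR low-pass
#' (Hamming-window design, applied forward and backward so SCR rise and decay
#' timing is unbiased).
#'
#' @param stream Single-channel EDA [signal_stream()] in microSiemens with
#'   `fs <= cfg$target_fs`.
#' @param cfg An [eda_config()].
#' @return A [signal_stream()] at `cfg$target_fs`.
#' @export
preprocess_eda <- function(stream, cfg = eda_config()) {
  stopifnot(inherits(stream, "signal_stream"), ncol(stream$samples) == 1)
  if (stream$fs > cfg$target_fs + 1e-9) {
    stop("downsampling unsupported: stream is at ", stream$fs,
         " Hz, target is ", cfg$target_fs, " Hz", call. = FALSE)
  }
  segs <- stream_segments(stream)
  out <- lapply(segs, .preprocess_segment, cfg = cfg)
  .rebuild_gapped(stream, out, cfg$target_fs)
}

.preprocess_segment <- function(seg, cfg) {
  n <- n_samples(seg)
  if (n == 0) {
    return(signal_stream(seg$start_unix, cfg$target_fs, numeric(0),
                         seg$channel_names, seg$units))
  }
  x <- seg$samples[, 1]
  t_in <- (seq_len(n) - 1) / seg$fs
  dur <- n / seg$fs
  n_out <- round(dur * cfg$target_fs)
  t_out <- (seq_len(n_out) - 1) / cfg$target_fs
  y <- if (n == 1) rep(x, n_out) else {
    stats::approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
  }
  if (length(y) > 3 * cfg$filter_taps) {
    h <- signal::fir1(cfg$filter_taps - 1,
                      cfg$filter_cutoff / (cfg$target_fs / 2),
                      type = "low", window = signal::hamming(cfg$filter_taps))
    h <- h / sum(h) # unit DC gain: a constant signal passes unchanged
    # A linear-phase FIR applied centered is zero-phase; replicate the
    # endpoints so boundaries do not ring.
    half <- (cfg$filter_taps - 1) %/% 2
    padded <- c(rep(y[1], half), y, rep(y[length(y)], cfg$filter_taps - 1 - half))
    y <- stats::filter(padded, h, method = "convolution", sides = 1)
    y <- as.numeric(y[(cfg$filter_taps):(length(padded))])
  }
  signal_stream(seg$start_unix, cfg$target_fs, y, seg$channel_names, seg$units)
}

# Reassemble per-segment outputs into one stream preserving the gap list.
.rebuild_gapped <- function(orig, segs, fs) {
  if (length(segs) == 1) return(segs[[1]])
  samples <- do.call(rbind, lapply(segs, `[[`, "samples"))
  signal_stream(segs[[1]]$start_unix, fs, samples,
                segs[[1]]$channel_names, segs[[1]]$units, gaps = orig$gaps)
}

#' Per-sample validity mask for an EDA stream
#'
#' Values near zero indicate electrode lift-off and values above the device
#' range indicate saturation; both are excluded from peak detection and
#' summaries, following standard skin-conductance quality rules.
#'
#' @param stream EDA [signal_stream()] in microSiemens.
#' @param cfg An [eda_config()] supplying `valid_min` / `valid_max`.
#' @return Logical vector, `TRUE` where the sample is analyzable.
#' @export
apply_validity_rules <- function(stream, cfg = eda_config()) {
  v <- stream$samples[, 1]
  v >= cfg$valid_min & v <= cfg$valid_max
}

# Haar detail coefficients over non-overlapping windows of `scale` seconds.
.haar_details <- function(x, fs, scale) {
  L <- max(2L, 2L * floor(fs * scale / 2))
  nwin <- floor(length(x) / L)
  if (nwin == 0) return(numeric(0))
  h <- L %/% 2L
  vapply(seq_len(nwin), function(k) {
    w <- x[((k - 1) * L + 1):(k * L)]
    (mean(w[1:h]) - mean(w[(h + 1):L])) * sqrt(L) / 2
  }, numeric(1))
}

#' Epoch-level EDA features for artifact screening
#'
#' Cuts the preprocessed stream into consecutive `epoch_len`-second epochs
#' (trailing partial epochs and epochs overlapping recorded gaps are
#' dropped) and computes, per epoch: raw statistics (mean, max, min, max
#' absolute first and second difference) and Haar wavelet detail statistics
#' at the one-second and half-second scales (max, mean of absolute
#' coefficients, and count of coefficients above 0.01).
#'
#' @param stream Preprocessed EDA [signal_stream()] at `cfg$target_fs`.
#' @param cfg An [eda_config()].
#' @return Data frame with one row per complete epoch (`epoch_index` is
#'   0-based) plus columns `t_start` (absolute Unix seconds).
#' @export
epoch_eda_features <- function(stream, cfg = eda_config()) {
  len <- cfg$epoch_len
  fs <- stream$fs
  per <- round(len * fs)
  t <- stream_times(stream)
  empty <- data.frame(epoch_index = integer(0), t_start = numeric(0),
                      mean = numeric(0), max = numeric(0), min = numeric(0),
                      max_abs_d1 = numeric(0), max_abs_d2 = numeric(0),
                      w1_max = numeric(0), w1_mean = numeric(0), w1_count = numeric(0),
                      w05_max = numeric(0), w05_mean = numeric(0), w05_count = numeric(0))
  if (length(t) < per) return(empty)
  span_end <- t[length(t)] + 1 / fs
  n_epochs <- floor((span_end - t[1] + 1e-9) / len)
  if (n_epochs == 0) return(empty)
  rows <- vector("list", n_epochs)
  kept <- 0L
  for (e in seq_len(n_epochs) - 1L) {
    t0 <- t[1] + e * len
    idx <- which(t >= t0 - 1e-9 & t < t0 + len - 1e-9)
    if (length(idx) != per) next # overlaps a recorded gap
    x <- stream$samples[idx, 1]
    d1 <- if (per > 1) diff(x) else 0
    d2 <- if (per > 2) diff(x, differences = 2) else 0
    w1 <- abs(.haar_details(x, fs, 1))
    w05 <- abs(.haar_details(x, fs, 0.5))
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      epoch_index = e, t_start = t0,
      mean = mean(x), max = max(x), min = min(x),
      max_abs_d1 = max(abs(d1)), max_abs_d2 = max(abs(d2)),
      w1_max = if (length(w1)) max(w1) else 0,
      w1_mean = if (length(w1)) mean(w1) else 0,
      w1_count = sum(w1 > 0.01),
      w05_max = if (length(w05)) max(w05) else 0,
      w05_mean = if (length(w05)) mean(w05) else 0,
      w05_count = sum(w05 > 0.01))
  }
  if (kept == 0) return(empty)
  do.call(rbind, rows[seq_len(kept)])
}

#' Classify 5-second EDA epochs as artifact / unclear / clean
#'
#' The original screening algorithm is a support vector machine trained on
#' expert-labeled data whose weights are not distributed; this function is
#' therefore pluggable. With `model = NULL` a documented rule set is used:
#' an epoch is an artifact when its maximum per-sample jump exceeds 10
#' microSiemens per second, or when its range exceeds both 20% of the
#' whole-signal range and 1 microSiemens (genuine SCRs rarely exceed ~1 uS
#' in 5 s, sensor artifacts routinely do). In ternary mode, epochs above
#' half of either threshold are labeled `"unclear"`.
#'
#' A custom `model` is a linear decision function:
#' `list(weights = <named numeric over feature columns>, bias = <numeric>,
#' margin = <numeric, ternary band half-width>)`; epochs with
#' `sum(w * f) + bias > 0` are artifacts, and in ternary mode scores in
#' `(-margin, 0]` are `"unclear"`.
#'
#' @param features Data frame from [epoch_eda_features()].
#' @param cfg An [eda_config()] (supplies `classifier_mode`).
#' @param model Optional linear model as described above.
#' @return Data frame with `epoch_index`, `t_start`, `label`.
#' @export
classify_eda_artifacts <- function(features, cfg = eda_config(), model = NULL) {
  n <- nrow(features)
  if (n == 0) {
    return(data.frame(epoch_index = integer(0), t_start = numeric(0),
                      label = character(0)))
  }
  ternary <- identical(cfg$classifier_mode, "ternary")
  if (!is.null(model)) {
    wn <- names(model$weights)
    if (is.null(wn) || !all(wn %in% names(features))) {
      stop("model mismatch: model weights name features absent from the table",
           call. = FALSE)
    }
    score <- as.matrix(features[wn]) %*% model$weights + model$bias
    label <- ifelse(score > 0, "artifact", "clean")
    if (ternary) {
      margin <- if (is.null(model$margin)) 0 else model$margin
      label[score <= 0 & score > -margin] <- "unclear"
    }
  } else {
    fs <- cfg$target_fs
    slope <- features$max_abs_d1 * fs           # uS per second
    rng <- features$max - features$min
    global_range <- max(features$max) - min(features$min)
    hard <- slope > 10 | (rng > 0.2 * global_range & rng > 1)
    label <- ifelse(hard, "artifact", "clean")
    if (ternary) {
      soft <- !hard & (slope > 5 | (rng > 0.1 * global_range & rng > 0.5))
      label[soft] <- "unclear"
    }
  }
  data.frame(epoch_index = features$epoch_index, t_start = features$t_start,
             label = label)
}

#' Detect skin-conductance-response peaks and compute their features
#'
#' Peak geometry follows the standard SCR definitions: the peak starts at
#' the last local minimum before a rising limb, the apex is the following
#' local maximum, and the amplitude is apex value minus start value. Only
#' peaks with amplitude at or above `cfg$peak_amplitude_threshold` are
#' reported. Peaks whose rise overlaps an artifact-labeled epoch or an
#' invalid sample (see [apply_validity_rules()]) are excluded. When the
#' signal recovers to half the amplitude before the next peak begins, the
#' half-recovery point defines `decay_time` (half-recovery minus apex),
#' `width` (time between the half-amplitude crossings of the rising and
#' falling limbs) and `auc` (trapezoidal integral of the signal above the
#' start level from start to half-recovery); otherwise those fields are `NA`.
#'
#' @param stream Preprocessed EDA [signal_stream()].
#' @param cfg An [eda_config()].
#' @param labels Optional data frame from [classify_eda_artifacts()].
#' @return Data frame, one row per peak: `start_time`, `apex_time`,
#'   `half_recovery_time`, `eda_at_start`, `amplitude`, `rise_time`,
#'   `max_derivative`, `decay_time`, `width`, `auc`. Times are absolute Unix
#'   seconds.
#' @export
detect_scr_peaks <- function(stream, cfg = eda_config(), labels = NULL) {
  segs <- stream_segments(stream)
  out <- lapply(segs, .detect_peaks_segment, cfg = cfg, labels = labels)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_peaks()
  res
}

.empty_peaks <- function() {
  data.frame(start_time = numeric(0), apex_time = numeric(0),
             half_recovery_time = numeric(0), eda_at_start = numeric(0),
             amplitude = numeric(0), rise_time = numeric(0),
             max_derivative = numeric(0), decay_time = numeric(0),
             width = numeric(0), auc = numeric(0))
}

.detect_peaks_segment <- function(seg, cfg, labels) {
  v <- seg$samples[, 1]
  n <- length(v)
  if (n < 3) return(.empty_peaks())
  t <- stream_times(seg)
  fs <- seg$fs
  valid <- apply_validity_rules(seg, cfg)

  d <- diff(v)
  # local extrema on the smoothed signal; plateaus resolved to their edges
  is_max <- c(FALSE, d[-(n - 1)] > 0 & d[-1] <= 0, FALSE) |
    c(FALSE, d[-(n - 1)] >= 0 & d[-1] < 0, FALSE)
  is_min <- c(TRUE, d[-(n - 1)] < 0 & d[-1] >= 0, FALSE) |
    c(TRUE, d[-(n - 1)] <= 0 & d[-1] > 0, FALSE)
  maxima <- which(is_max)
  minima <- which(is_min)
  if (length(maxima) == 0) return(.empty_peaks())

  art_windows <- NULL
  if (!is.null(labels) && nrow(labels) > 0) {
    art <- labels[labels$label == "artifact", , drop = FALSE]
    if (nrow(art) > 0) {
      art_windows <- cbind(art$t_start, art$t_start + cfg$epoch_len)
    }
  }
  overlaps_artifact <- function(t0, t1) {
    if (is.null(art_windows)) return(FALSE)
    any(t0 < art_windows[, 2] & t1 > art_windows[, 1])
  }

  rows <- list()
  for (a in maxima) {
    pre <- minima[minima < a]
    if (length(pre) == 0) next
    s <- max(pre)
    amp <- v[a] - v[s]
    if (amp < cfg$peak_amplitude_threshold) next
    if (any(!valid[s:a])) next
    if (overlaps_artifact(t[s], t[a])) next

    half <- v[s] + amp / 2
    rise_idx <- s:a
    cross_up <- which(v[rise_idx] >= half)[1]
    t_up <- if (is.na(cross_up) || cross_up == 1) t[s] else {
      i2 <- rise_idx[cross_up]; i1 <- i2 - 1
      t[i1] + (half - v[i1]) / (v[i2] - v[i1]) * (t[i2] - t[i1])
    }

    nxt_min <- minima[minima > a]
    nxt_max <- maxima[maxima > a]
    # search for half recovery until the start of the next reported rise
    search_end <- n
    if (length(nxt_max) > 0) {
      nm <- nxt_max[1]
      pre2 <- minima[minima < nm & minima > a]
      if (length(pre2) > 0 && v[nm] - v[max(pre2)] >= cfg$peak_amplitude_threshold) {
        search_end <- max(pre2)
      }
    }
    t_half <- NA_real_; decay <- NA_real_; width <- NA_real_; auc <- NA_real_
    if (search_end > a) {
      post <- (a + 1):search_end
      below <- which(v[post] <= half)[1]
      if (!is.na(below)) {
        i2 <- post[below]; i1 <- i2 - 1
        frac <- if (v[i2] == v[i1]) 0 else (v[i1] - half) / (v[i1] - v[i2])
        t_half <- t[i1] + frac * (t[i2] - t[i1])
        decay <- t_half - t[a]
        width <- t_half - t_up
        # trapezoid of (v - v[s]) from start to the interpolated half point
        ti <- c(t[s:i1], t_half)
        vi <- c(v[s:i1], half) - v[s]
        auc <- sum(diff(ti) * (utils::head(vi, -1) + utils::tail(vi, -1)) / 2)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      start_time = t[s], apex_time = t[a], half_recovery_time = t_half,
      eda_at_start = v[s], amplitude = amp, rise_time = t[a] - t[s],
      max_derivative = max(d[s:(a - 1)]) * fs,
      decay_time = decay, width = width, auc = auc)
  }
  if (length(rows) == 0) return(.empty_peaks())
  do.call(rbind, rows)
}

#' Skin-conductance responses per minute
#'
#' @param peaks Data frame from [detect_scr_peaks()].
#' @param analyzed_duration Analyzable duration in seconds (valid,
#'   artifact-free time only).
#' @return Peaks per minute.
#' @export
peaks_per_minute <- function(peaks, analyzed_duration) {
  if (!is.numeric(analyzed_duration) || analyzed_duration <= 0) {
    stop("no analyzable data", call. = FALSE)
  }
  nrow(peaks) / (analyzed_duration / 60)
}
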