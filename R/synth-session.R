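# Seeded synthetic-session generator with ground truth.
#
# Emulates the signal structure an E4 recording exhibits: skin conductance
# responses (SCRs) over a slowly varying tonic baseline, a plausible RR
# series with optional anomalies, movement bursts over 1 g rest, and a warm
# wrist-skin temperature. Every generated quantity carries ground truth so
# detectors can be scored without any real recording.

#' Synthetic session specification
#'
#' Defaults describe a quiet resting recording: tonic skin conductance of
#' 2 microSiemens with noise at the device quantization floor (the device
#' resolves ~0.9 nanoSiemens per digit; quantization noise has standard
#' deviation step/sqrt(12), about 0.00026 uS), resting heart rate of 70 bpm
#' with 20 ms beat jitter, wrist skin temperature of 33 degrees Celsius,
#' and a device at rest (1 g) outside the requested movement bursts.
#'
#' @param duration Session duration in seconds.
#' @param seed Integer seed; identical specs generate identical sessions.
#' @param scr_events Data frame with columns `time` (s), `amplitude` (uS),
#'   `rise` (s), `decay` (s, exponential decay constant). Events must be
#'   separated by more than `rise + 3 * decay`.
#' @param baseline_eda Tonic level in microSiemens.
#' @param eda_noise_sd Gaussian noise SD in microSiemens.
#' @param artifact_epochs Data frame with columns `epoch` (0-based 5-s epoch
#'   index) and `kind` (`"step"`, `"dropout"`, `"spike"`).
#' @param mean_hr Mean heart rate in bpm.
#' @param hr_jitter_sd Beat-to-beat jitter SD in milliseconds.
#' @param rr_anomalies Data frame with columns `index` (1-based interval
#'   index) and `kind` (`"missed"` merges two intervals, `"ectopic_short"`
#'   halves one).
#' @param movement_bursts Data frame with columns `start`, `end` (s) and
#'   `g` (mean magnitude during the burst).
#' @param temp_baseline Skin temperature in degrees Celsius.
#' @param tags Optional numeric vector of event-marker times (s from start).
#' @param start_unix Recording start (Unix seconds UTC).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration = 300, seed = 42,
                       scr_events = NULL,
                       baseline_eda = 2, eda_noise_sd = 0.00026,
                       artifact_epochs = NULL,
                       mean_hr = 70, hr_jitter_sd = 20,
                       rr_anomalies = NULL,
                       movement_bursts = NULL,
                       temp_baseline = 33,
                       tags = NULL,
                       start_unix = 1581000000) {
  stopifnot(duration > 0, mean_hr > 0, mean_hr < 300, hr_jitter_sd >= 0,
            eda_noise_sd >= 0, baseline_eda >= 0)
  if (is.null(scr_events)) {
    scr_events <- data.frame(time = numeric(0), amplitude = numeric(0),
                             rise = numeric(0), decay = numeric(0))
  }
  if (nrow(scr_events) > 0) {
    stopifnot(all(scr_events$amplitude > 0), all(scr_events$rise > 0),
              all(scr_events$decay > 0))
    o <- order(scr_events$time)
    scr_events <- scr_events[o, , drop = FALSE]
    if (nrow(scr_events) > 1) {
      sep_needed <- scr_events$rise[-nrow(scr_events)] +
        3 * scr_events$decay[-nrow(scr_events)]
      if (any(diff(scr_events$time) <= sep_needed)) {
        stop("events too close: SCRs must be separated by more than rise + 3*decay",
             call. = FALSE)
      }
    }
  }
  if (is.null(artifact_epochs)) {
    artifact_epochs <- data.frame(epoch = integer(0), kind = character(0))
  }
  if (is.null(rr_anomalies)) {
    rr_anomalies <- data.frame(index = integer(0), kind = character(0))
  }
  if (is.null(movement_bursts)) {
    movement_bursts <- data.frame(start = numeric(0), end = numeric(0),
                                  g = numeric(0))
  }
  structure(list(duration = duration, seed = as.integer(seed),
                 scr_events = scr_events, baseline_eda = baseline_eda,
                 eda_noise_sd = eda_noise_sd,
                 artifact_epochs = artifact_epochs,
                 mean_hr = mean_hr, hr_jitter_sd = hr_jitter_sd,
                 rr_anomalies = rr_anomalies,
                 movement_bursts = movement_bursts,
                 temp_baseline = temp_baseline,
                 tags = tags, start_unix = start_unix),
            class = "synth_spec")
}

# Run fn with a deterministic RNG state derived from (seed, salt), restoring
# the caller's RNG state afterwards.
.with_seed <- function(seed, salt, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed((seed * 131 + salt) %% .Machine$integer.max)
  fn()
}

# SCR kernel: linear rise to the amplitude over `rise` seconds, then
# exponential decay with time constant `decay`.
.scr_kernel <- function(t, t0, amplitude, rise, decay) {
  dt <- t - t0
  out <- numeric(length(t))
  up <- dt >= 0 & dt < rise
  down <- dt >= rise
  out[up] <- amplitude * dt[up] / rise
  out[down] <- amplitude * exp(-(dt[down] - rise) / decay)
  out
}

#' Generate a synthetic EDA stream with an SCR train
#'
#' Builds a 4 Hz EDA stream as baseline + sum of SCR kernels (linear rise,
#' exponential decay) + Gaussian noise, with optional injected artifact
#' epochs (a 5 uS step, a dropout to zero, or an 8 uS single-sample spike).
#'
#' @param spec A [synth_spec()].
#' @return List: `stream` (4 Hz [signal_stream()] in uS) and `truth`, a data
#'   frame of the true SCR start times, apex times and amplitudes.
#' @export
synth_scr_train <- function(spec) {
  fs <- 4
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  v <- rep(spec$baseline_eda, length(t))
  ev <- spec$scr_events
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      v <- v + .scr_kernel(t, ev$time[i], ev$amplitude[i], ev$rise[i], ev$decay[i])
    }
  }
  if (spec$eda_noise_sd > 0) {
    noise <- .with_seed(spec$seed, 1, function() {
      stats::rnorm(length(t), 0, spec$eda_noise_sd)
    })
    v <- v + noise
  }
  ae <- spec$artifact_epochs
  if (nrow(ae) > 0) {
    epoch_len <- 5
    for (i in seq_len(nrow(ae))) {
      lo <- ae$epoch[i] * epoch_len
      sel <- t >= lo & t < lo + epoch_len
      v[sel] <- switch(as.character(ae$kind[i]),
        step = v[sel] + 5,
        dropout = 0,
        spike = { w <- v[sel]; w[ceiling(length(w) / 2)] <-
                    w[ceiling(length(w) / 2)] + 8; w },
        stop("unknown artifact kind: ", ae$kind[i], call. = FALSE))
    }
  }
  truth <- data.frame(start_time = ev$time, apex_time = ev$time + ev$rise,
                      amplitude = ev$amplitude)
  list(stream = signal_stream(spec$start_unix, fs, v, "eda", "uS"),
       truth = truth)
}

#' Generate a synthetic RR series
#'
#' Intervals are `60/mean_hr` seconds plus Gaussian jitter. A `"missed"`
#' anomaly at interval `i` replaces intervals `i` and `i+1` with their sum
#' (emulating an undetected beat); `"ectopic_short"` halves interval `i`.
#'
#' @param spec A [synth_spec()].
#' @return List: `series` (an [rr_series()]) and `truth`, a data frame of
#'   the injected anomalies with the offsets of the affected beats.
#' @export
synth_rr_series <- function(spec) {
  base <- 60 / spec$mean_hr
  n <- ceiling(spec$duration / base) + 1
  jit <- if (spec$hr_jitter_sd > 0) {
    .with_seed(spec$seed, 2, function() stats::rnorm(n, 0, spec$hr_jitter_sd / 1000))
  } else numeric(n)
  intervals <- pmax(base + jit, 0.2)
  an <- spec$rr_anomalies
  truth <- data.frame(offset = numeric(0), kind = character(0))
  if (nrow(an) > 0) {
    drop_idx <- integer(0)
    for (i in seq_len(nrow(an))) {
      k <- an$index[i]
      if (k >= length(intervals)) next
      if (an$kind[i] == "missed") {
        intervals[k] <- intervals[k] + intervals[k + 1]
        drop_idx <- c(drop_idx, k + 1L)
      } else if (an$kind[i] == "ectopic_short") {
        intervals[k] <- intervals[k] / 2
      } else {
        stop("unknown anomaly kind: ", an$kind[i], call. = FALSE)
      }
    }
    if (length(drop_idx) > 0) intervals <- intervals[-drop_idx]
    offs_tmp <- cumsum(intervals)
    truth <- data.frame(offset = offs_tmp[pmin(an$index, length(offs_tmp))],
                        kind = an$kind)
  }
  offsets <- cumsum(intervals)
  keep <- offsets <= spec$duration
  list(series = rr_series(spec$start_unix, offsets[keep], intervals[keep]),
       truth = truth)
}

# Internal: supporting streams for a full archive.
.synth_acc_stream <- function(spec) {
  fs <- 32
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  noise <- .with_seed(spec$seed, 3, function() {
    matrix(stats::rnorm(3 * n, 0, 0.5), ncol = 3)
  })
  samples <- cbind(rep(0, n), rep(0, n), rep(64, n)) + noise # rest: 1 g on z
  mb <- spec$movement_bursts
  if (nrow(mb) > 0) {
    for (i in seq_len(nrow(mb))) {
      sel <- t >= mb$start[i] & t < mb$end[i]
      # oscillation about the requested mean magnitude
      wob <- 4 * sin(2 * pi * 2 * t[sel])
      samples[sel, 3] <- mb$g[i] * 64 + wob
    }
  }
  signal_stream(spec$start_unix, fs, round(samples),
                c("x", "y", "z"), c("counts", "counts", "counts"))
}

.synth_temp_stream <- function(spec) {
  fs <- 32
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  drift <- 0.2 * sin(2 * pi * t / max(spec$duration, 1))
  noise <- .with_seed(spec$seed, 4, function() stats::rnorm(length(t), 0, 0.02))
  signal_stream(spec$start_unix, fs, spec$temp_baseline + drift + noise,
                "temp", "degC")
}

.synth_hr_stream <- function(spec, series) {
  fs <- 1
  t <- seq(0, spec$duration - 1, by = 1)
  hr <- if (n_beats(series) >= 2) {
    stats::approx(series$beat_offsets, 60 / series$intervals,
                  xout = t, rule = 2)$y
  } else rep(spec$mean_hr, length(t))
  signal_stream(spec$start_unix, fs, hr, "hr", "bpm")
}

.synth_bvp_stream <- function(spec) {
  fs <- 64
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  f0 <- spec$mean_hr / 60
  # placeholder pulse waveform: fundamental plus two harmonics at beat rate
  v <- 50 * sin(2 * pi * f0 * t) + 20 * sin(2 * pi * 2 * f0 * t + 0.8) +
    8 * sin(2 * pi * 3 * f0 * t + 1.9)
  signal_stream(spec$start_unix, fs, v, "bvp", "raw")
}

#' Build a full synthetic session
#'
#' @param spec A [synth_spec()].
#' @return List with `session` (an [e4_session()] holding all six streams)
#'   and `truth` (SCR, RR-anomaly and artifact-epoch ground truth).
#' @export
synth_session <- function(spec) {
  eda <- synth_scr_train(spec)
  rr <- synth_rr_series(spec)
  session <- e4_session(
    eda = eda$stream,
    bvp = .synth_bvp_stream(spec),
    hr = .synth_hr_stream(spec, rr$series),
    temp = .synth_temp_stream(spec),
    acc = .synth_acc_stream(spec),
    ibi = rr$series,
    tags = if (!is.null(spec$tags)) spec$start_unix + spec$tags else NULL,
    source_names = "synthetic")
  truth <- list(scr = eda$truth, rr_anomalies = rr$truth,
                artifact_epochs = spec$artifact_epochs,
                movement_bursts = spec$movement_bursts,
                spec_seed = spec$seed)
  list(session = session, truth = truth)
}

#' Write a synthetic session archive with a ground-truth sidecar
#'
#' Writes a zip in the exact E4 dialect (EDA 4 Hz, BVP 64 Hz placeholder,
#' HR 1 Hz derived from the RR series, TEMP and ACC 32 Hz, two-column IBI,
#' optional tags) plus a JSON sidecar `<path minus .zip>.truth.json` with
#' the ground truth for every detector.
#'
#' @param spec A [synth_spec()].
#' @param path Output zip path.
#' @return `path`, invisibly; the session/truth list as attribute `"built"`.
#' @export
synth_session_zip <- function(spec, path) {
  built <- synth_session(spec)
  write_session(built$session, path)
  sidecar <- sub("\\.zip$", "", path)
  jsonlite::write_json(built$truth, paste0(sidecar, ".truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- invisible(path)
  attr(out, "built") <- built
  invisible(out)
}
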