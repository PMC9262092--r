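# Cutting sessions into fixed-width bins and batch-processing archives.

#' Cut specification
#'
#' @param start,end Analysis timeframe in seconds relative to the session
#'   start (`end > start`).
#' @param bin_width Bin width in seconds, at most `end - start`. Bins are
#'   half-open `[t, t + bin_width)` so no sample lands in two bins; a
#'   partial trailing bin is dropped.
#' @return A list of class `cut_spec`.
#' @export
cut_spec <- function(start, end, bin_width) {
  stopifnot(end > start, bin_width > 0, bin_width <= end - start)
  structure(list(start = start, end = end, bin_width = bin_width),
            class = "cut_spec")
}

# Slice a session to the window [from, to) in session-relative seconds,
# rebasing all streams, beats and tags to the window start.
session_window <- function(session, from, to) {
  span <- session_span(session)
  abs_from <- span[1] + from
  abs_to <- span[1] + to
  args <- list(source_names = session$source_names, tz_offset = session$tz_offset)
  for (nm in session_stream_names(session)) {
    args[[nm]] <- stream_window(session[[nm]], abs_from, abs_to)
  }
  if (!is.null(session$ibi)) {
    r <- session$ibi
    abs_beat <- r$start_unix + r$beat_offsets
    keep <- abs_beat >= abs_from - 1e-9 & abs_beat < abs_to - 1e-9
    args$ibi <- rr_series(abs_from, abs_beat[keep] - abs_from,
                          r$intervals[keep], r$accepted[keep])
  }
  if (!is.null(session$tags)) {
    keep <- session$tags >= abs_from & session$tags < abs_to
    if (any(keep)) args$tags <- session$tags[keep]
  }
  do.call(e4_session, args)
}

#' Cut a session into fixed-width bins
#'
#' Divides the timeframe `[spec$start, spec$end)` into
#' `floor((end - start) / bin_width)` half-open bins. Each bin is a valid
#' session whose streams are rebased to the bin start (so it can be written
#' with [write_session()] as an E4-dialect archive); IBI beat offsets are
#' rebased likewise. The canonical worked example: a 30-minute timeframe
#' with 5-minute bins yields 6 archives.
#'
#' @param session An [e4_session()].
#' @param spec A [cut_spec()].
#' @return List of [e4_session()] bins, with attribute `dropped_seconds`
#'   giving the length of any dropped partial trailing bin.
#' @export
cut_session <- function(session, spec) {
  span <- session_span(session)
  total <- span[2] - span[1]
  if (spec$start < -1e-9 || spec$start >= total || spec$end > total + 1e-6) {
    stop("out of range: timeframe [", spec$start, ", ", spec$end,
         ") outside the session span of ", round(total, 3), " s",
         call. = FALSE)
  }
  n_bins <- floor((spec$end - spec$start) / spec$bin_width + 1e-9)
  dropped <- (spec$end - spec$start) - n_bins * spec$bin_width
  if (dropped > 1e-9) {
    message("dropping partial trailing bin of ", round(dropped, 3), " s")
  }
  bins <- lapply(seq_len(n_bins) - 1, function(k) {
    session_window(session,
                   spec$start + k * spec$bin_width,
                   spec$start + (k + 1) * spec$bin_width)
  })
  attr(bins, "dropped_seconds") <- max(0, dropped)
  bins
}

#' Summarize one analysis interval of a session
#'
#' Runs the full pipeline on the window `[start, end)` (session-relative
#' seconds): EDA preprocessing, epoch artifact classification, validity
#' masking and peak detection; RR plausibility filtering and time-domain
#' HRV; movement magnitude; temperature. High movement overlapping the
#' interval sets `movement_present`, since HRV should only be interpreted
#' in resting, non-movement conditions.
#'
#' @param session An [e4_session()].
#' @param start,end Interval in seconds relative to session start.
#' @param configs Optional list with elements `eda` ([eda_config()]),
#'   `rr` ([rr_filter_config()]), `movement` ([movement_config()]).
#' @return A list of class `summary_row`: `mean_eda`, `peaks_per_min`,
#'   `mean_hr`, `rmssd`, `mean_temp`, `mean_movement`,
#'   `eda_artifact_fraction`, `beat_acceptance_fraction`,
#'   `movement_present`, plus per-signal `mean/min/max/median` summaries
#'   under `signal_summaries`.
#' @export
summarize_interval <- function(session, start, end, configs = list()) {
  stopifnot(end > start)
  eda_cfg <- configs$eda %||% eda_config()
  rr_cfg <- configs$rr %||% rr_filter_config()
  mv_cfg <- configs$movement %||% movement_config()

  win <- session_window(session, start, end)
  has_data <- FALSE
  out <- list(mean_eda = NA_real_, peaks_per_min = NA_real_,
              mean_hr = NA_real_, rmssd = NA_real_,
              mean_temp = NA_real_, mean_movement = NA_real_,
              eda_artifact_fraction = NA_real_,
              beat_acceptance_fraction = NA_real_,
              movement_present = FALSE,
              signal_summaries = list(),
              peaks = .empty_peaks(), epoch_labels = NULL, rr_filter = NULL)

  if (!is.null(win$eda) && n_samples(win$eda) > 0) {
    has_data <- TRUE
    proc <- preprocess_eda(win$eda, eda_cfg)
    mask <- apply_validity_rules(proc, eda_cfg)
    feats <- epoch_eda_features(proc, eda_cfg)
    labels <- classify_eda_artifacts(feats, eda_cfg)
    peaks <- detect_scr_peaks(proc, eda_cfg, labels)
    n_art <- sum(labels$label == "artifact")
    art_frac <- if (nrow(labels) > 0) n_art / nrow(labels) else NA_real_
    analyzable <- sum(mask) / proc$fs - n_art * eda_cfg$epoch_len
    out$mean_eda <- if (any(mask)) mean(proc$samples[mask, 1]) else NA_real_
    out$eda_artifact_fraction <- art_frac
    out$peaks <- peaks
    out$epoch_labels <- labels
    out$peaks_per_min <- if (analyzable > 0) {
      peaks_per_minute(peaks, analyzable)
    } else NA_real_
    if (any(mask)) {
      out$signal_summaries$eda <- summarize_stream(proc, mask)
    }
  }

  if (!is.null(win$ibi) && n_beats(win$ibi) > 0) {
    has_data <- TRUE
    fr <- filter_rr(win$ibi, rr_cfg)
    out$rr_filter <- fr
    out$beat_acceptance_fraction <-
      if (fr$n_original > 0) fr$n_accepted / fr$n_original else NA_real_
    if (fr$n_accepted >= 2) {
      td <- hrv_time_domain(fr$series)
      out$mean_hr <- td$mean_hr
      out$rmssd <- td$rmssd
    }
  }
  if (is.na(out$mean_hr) && !is.null(win$hr) && n_samples(win$hr) > 0) {
    has_data <- TRUE
    out$mean_hr <- mean(win$hr$samples[, 1])
  }
  if (!is.null(win$hr) && n_samples(win$hr) > 0) {
    out$signal_summaries$hr <- summarize_stream(win$hr)
  }

  if (!is.null(win$temp) && n_samples(win$temp) > 0) {
    has_data <- TRUE
    out$signal_summaries$temp <- summarize_stream(win$temp)
    out$mean_temp <- out$signal_summaries$temp$mean
  }

  if (!is.null(win$acc) && n_samples(win$acc) > 0) {
    has_data <- TRUE
    mag <- acc_mean_magnitude(win$acc, mv_cfg)
    out$signal_summaries$movement <- summarize_stream(mag)
    out$mean_movement <- out$signal_summaries$movement$mean
    out$movement_present <- nrow(flag_high_movement(mag, mv_cfg)) > 0
  }

  if (!has_data) stop("no analyzable data", call. = FALSE)
  structure(out, class = "summary_row")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch-process a folder of session archives
#'
#' Processes every `.zip` in `input_dir` with [summarize_interval()] over
#' the whole session and writes one result container per archive to
#' `output_dir`, named `<stem>_results.zip` (the stem is the input archive
#' name, so results trace back to the recording). Each container holds
#' `result.json` (session metadata, summaries, HRV, artifact fractions),
#' `peaks.csv` (one SCR per row) and `epoch_labels.csv`. Failures on one
#' archive are logged and skipped; a `manifest.json` in `output_dir` lists
#' successes and failures.
#'
#' @param input_dir Folder containing session zips.
#' @param output_dir Output folder (created if absent).
#' @param configs Config list as for [summarize_interval()].
#' @param tz_offset Display-timezone offset in minutes.
#' @return The manifest (list with `succeeded`, `failed`), invisibly.
#' @export
batch_process <- function(input_dir, output_dir, configs = list(),
                          tz_offset = 0) {
  zips <- list.files(input_dir, pattern = "\\.zip$", full.names = TRUE)
  zips <- zips[!grepl("_results\\.zip$", zips)]
  if (length(zips) == 0) stop("nothing to process in ", input_dir, call. = FALSE)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  succeeded <- character(0)
  failed <- list()
  for (z in zips) {
    stem <- sub("\\.zip$", "", basename(z))
    res <- tryCatch({
      session <- read_session(z, tz_offset = tz_offset)
      span <- session_span(session)
      row <- summarize_interval(session, 0, span[2] - span[1], configs)
      .write_batch_result(session, row, file.path(output_dir, paste0(stem, "_results.zip")))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) {
      succeeded <- c(succeeded, stem)
      message("processed ", stem)
    } else {
      failed[[stem]] <- res
      message("FAILED ", stem, ": ", res)
    }
  }
  manifest <- list(succeeded = succeeded,
                   failed = lapply(failed, identity))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.df_to_csv_lines <- function(df) {
  if (nrow(df) == 0) return(paste(names(df), collapse = ","))
  body <- apply(df, 1, function(r) paste(r, collapse = ","))
  c(paste(names(df), collapse = ","), body)
}

.write_batch_result <- function(session, row, path) {
  span <- session_span(session)
  meta <- list(
    source_names = session$source_names,
    start_unix = span[1], end_unix = span[2],
    start_display = format_session_time(span[1], session$tz_offset),
    duration_s = span[2] - span[1],
    summary = row[c("mean_eda", "peaks_per_min", "mean_hr", "rmssd",
                    "mean_temp", "mean_movement", "eda_artifact_fraction",
                    "beat_acceptance_fraction", "movement_present")],
    signal_summaries = row$signal_summaries,
    rr_filter = if (!is.null(row$rr_filter)) {
      list(n_original = row$rr_filter$n_original,
           n_accepted = row$rr_filter$n_accepted)
    } else NULL
  )
  members <- list(
    "result.json" = strsplit(as.character(
      jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")), "\n")[[1]],
    "peaks.csv" = .df_to_csv_lines(row$peaks)
  )
  if (!is.null(row$epoch_labels)) {
    members[["epoch_labels.csv"]] <- .df_to_csv_lines(row$epoch_labels)
  }
  zip_write(path, members)
}
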