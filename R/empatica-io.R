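# Reading and writing session archives in the Empatica E4 zip/CSV dialect.
#
# Every signal CSV carries the recording start (Unix time, UTC) in row 1 and
# the sampling frequency in row 2, with samples from row 3 onward; multi-
# channel files repeat the header values once per column. The IBI file is
# different: row 1 holds the Unix start time (second column is a label in
# device exports), and each following row is (seconds since start, interval).

.e4_files <- c(eda = "EDA.csv", bvp = "BVP.csv", hr = "HR.csv",
               temp = "TEMP.csv", acc = "ACC.csv")
.e4_units <- list(eda = "uS", bvp = "raw", hr = "bpm", temp = "degC",
                  acc = c("counts", "counts", "counts"))
.e4_channels <- list(eda = "eda", bvp = "bvp", hr = "hr", temp = "temp",
                     acc = c("x", "y", "z"))

.split_csv_line <- function(line) {
  trimws(strsplit(line, ",", fixed = TRUE)[[1]])
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Parse a signal CSV in the E4 dialect
#'
#' @param text Character vector of CSV lines (or a single string with
#'   embedded newlines).
#' @param n_channels Expected channel count, or `NULL` to infer from row 1.
#' @param channel_names,units Optional channel names and unit labels.
#' @param file Name used in error messages.
#' @return A [signal_stream()]. Sample `i` (0-based) covers
#'   `[start + i/fs, start + (i+1)/fs)`; e.g. each row of a 4 Hz file
#'   represents 250 ms of data.
#' @export
parse_signal_csv <- function(text, n_channels = NULL, channel_names = NULL,
                             units = "", file = "<text>") {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\r?\n")[[1]]
  }
  text <- text[nzchar(trimws(text))]
  if (length(text) < 2) {
    stop("bad dialect: ", file, " lacks the start-time/frequency header rows",
         call. = FALSE)
  }
  row1 <- .num_or_na(.split_csv_line(text[1]))
  row2 <- .num_or_na(.split_csv_line(text[2]))
  if (anyNA(row1) || anyNA(row2)) {
    stop("bad dialect: non-numeric header in ", file, call. = FALSE)
  }
  if (length(unique(row1)) != 1 || length(unique(row2)) != 1) {
    stop("bad dialect: inconsistent header columns in ", file, call. = FALSE)
  }
  start_unix <- row1[1]
  fs <- row2[1]
  if (is.na(fs) || fs <= 0) {
    stop("bad dialect: non-positive sampling frequency in ", file, call. = FALSE)
  }
  if (is.null(n_channels)) n_channels <- length(row1)
  payload <- text[-(1:2)]
  if (length(payload) == 0) {
    samples <- matrix(numeric(0), ncol = n_channels)
  } else {
    vals <- .num_or_na(unlist(lapply(payload, .split_csv_line), use.names = FALSE))
    if (anyNA(vals) || length(vals) %% n_channels != 0) {
      stop("bad dialect: non-numeric or ragged payload in ", file, call. = FALSE)
    }
    samples <- matrix(vals, ncol = n_channels, byrow = TRUE)
  }
  signal_stream(start_unix, fs, samples, channel_names, units)
}

#' Parse an IBI CSV in the E4 dialect
#'
#' @param text Character vector of CSV lines (or one string).
#' @param file Name used in error messages.
#' @return An [rr_series()] with all beats accepted. A second-column label in
#'   row 1 (e.g. `IBI`) is tolerated, as written by device exports.
#' @export
parse_ibi_csv <- function(text, file = "<text>") {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\r?\n")[[1]]
  }
  text <- text[nzchar(trimws(text))]
  if (length(text) < 1) stop("bad dialect: empty IBI file ", file, call. = FALSE)
  row1 <- .split_csv_line(text[1])
  start_unix <- .num_or_na(row1[1])
  if (is.na(start_unix)) {
    stop("bad dialect: non-numeric start time in ", file, call. = FALSE)
  }
  payload <- text[-1]
  if (length(payload) == 0) {
    return(rr_series(start_unix, numeric(0), numeric(0)))
  }
  cells <- lapply(payload, .split_csv_line)
  if (any(lengths(cells) != 2)) {
    stop("bad dialect: IBI rows must have two columns in ", file, call. = FALSE)
  }
  m <- matrix(.num_or_na(unlist(cells, use.names = FALSE)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("bad dialect: non-numeric IBI payload in ", file, call. = FALSE)
  rr_series(start_unix, m[, 1], m[, 2])
}

# Format numbers for the on-disk dialect: integers unpadded, floats with 6
# decimal places.
.e4_num <- function(x) {
  ifelse(is.finite(x) & x == round(x) & abs(x) < 1e15,
         sprintf("%.0f", x), sprintf("%.6f", x))
}

.serialize_signal_csv <- function(stream) {
  k <- ncol(stream$samples)
  header <- c(paste(rep(.e4_num(stream$start_unix), k), collapse = ","),
              paste(rep(.e4_num(stream$fs), k), collapse = ","))
  if (nrow(stream$samples) == 0) return(header)
  body <- apply(stream$samples, 1, function(r) paste(.e4_num(r), collapse = ","))
  c(header, body)
}

.serialize_ibi_csv <- function(series) {
  header <- paste0(.e4_num(series$start_unix), ",IBI")
  if (n_beats(series) == 0) return(header)
  c(header, paste(.e4_num(series$beat_offsets), .e4_num(series$intervals), sep = ","))
}

#' Read one or more E4 session archives
#'
#' Reads zip archives in the Empatica E4 dialect. When several archives are
#' given they must come from the same calendar day (in the display timezone)
#' and are merged chronologically with [merge_same_day()]; the user-facing
#' case is a device that was accidentally turned off, producing multiple
#' files per day.
#'
#' @param archive_paths Character vector of zip paths.
#' @param tz_offset Display-timezone offset in minutes (e.g. 120 for UTC+2).
#' @return An [e4_session()].
#' @export
read_session <- function(archive_paths, tz_offset = 0) {
  stopifnot(length(archive_paths) >= 1)
  sessions <- lapply(archive_paths, .read_one_archive, tz_offset = tz_offset)
  if (length(sessions) == 1) return(sessions[[1]])
  merge_same_day(sessions)
}

.read_one_archive <- function(path, tz_offset = 0) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("unreadable archive: ", path, call. = FALSE)
  }
  listing <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e) NULL,
                      warning = function(w) NULL)
  if (is.null(listing) || nrow(listing) == 0) {
    stop("unreadable archive: ", path, call. = FALSE)
  }
  exdir <- tempfile("e4x")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  extracted <- list.files(exdir, recursive = TRUE, full.names = TRUE)
  base_lower <- tolower(basename(extracted))

  find_file <- function(name) {
    hit <- which(base_lower == tolower(name))
    if (length(hit) == 0) NULL else extracted[hit[1]]
  }

  args <- list(source_names = basename(path), tz_offset = tz_offset)
  found_any <- FALSE
  for (nm in names(.e4_files)) {
    f <- find_file(.e4_files[[nm]])
    if (is.null(f)) next
    found_any <- TRUE
    args[[nm]] <- parse_signal_csv(readLines(f, warn = FALSE),
                                   n_channels = length(.e4_channels[[nm]]),
                                   channel_names = .e4_channels[[nm]],
                                   units = .e4_units[[nm]],
                                   file = basename(f))
  }
  f <- find_file("IBI.csv")
  if (!is.null(f)) {
    found_any <- TRUE
    args$ibi <- parse_ibi_csv(readLines(f, warn = FALSE), file = basename(f))
  }
  f <- find_file("tags.csv")
  if (!is.null(f)) {
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    tags <- .num_or_na(lines)
    if (anyNA(tags)) {
      warning("skipping non-numeric tag line(s) in ", basename(path))
      tags <- tags[!is.na(tags)]
    }
    args$tags <- tags
  }
  known <- c(tolower(.e4_files), "ibi.csv", "tags.csv", "info.txt")
  extra <- extracted[!(base_lower %in% known)]
  if (length(extra) > 0) {
    message("ignoring unrecognized member(s) in ", basename(path), ": ",
            paste(basename(extra), collapse = ", "))
  }
  if (!found_any) {
    stop("unreadable archive: ", path, " contains no recognized E4 CSVs",
         call. = FALSE)
  }
  do.call(e4_session, args)
}

#' Write a session archive in the E4 dialect
#'
#' Produces a zip readable by [read_session()]. Round trips preserve start
#' times, sampling frequencies, and sample values exactly at the on-disk
#' precision (floats with 6 decimals, integers unpadded). Sessions carrying
#' recorded gaps cannot be represented in the dialect and are refused.
#'
#' @param session An [e4_session()] with at least one stream or beat series.
#' @param path Output zip path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  members <- list()
  for (nm in session_stream_names(session)) {
    s <- session[[nm]]
    if (nrow(s$gaps) > 0) {
      stop("cannot serialize a stream with recorded gaps (", nm,
           "); cut the session into contiguous pieces first", call. = FALSE)
    }
    members[[.e4_files[[nm]]]] <- .serialize_signal_csv(s)
  }
  if (!is.null(session$ibi)) {
    members[["IBI.csv"]] <- .serialize_ibi_csv(session$ibi)
  }
  if (!is.null(session$tags) && length(session$tags) > 0) {
    members[["tags.csv"]] <- .e4_num(session$tags)
  }
  if (length(members) == 0) stop("session has no streams to write", call. = FALSE)
  zip_write(path, members)
}

#' Merge same-day sessions chronologically
#'
#' Concatenates the streams of several recordings from one calendar day.
#' The time between recordings is preserved as a *recorded gap* on each
#' stream (no samples are fabricated); IBI beat offsets are rebased to the
#' merged start. Input order does not matter.
#'
#' @param sessions List of [e4_session()]s sharing one calendar day in the
#'   display timezone.
#' @return A single merged [e4_session()].
#' @export
merge_same_day <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  if (length(sessions) == 1) return(sessions[[1]])
  spans <- lapply(sessions, session_span)
  ord <- order(vapply(spans, `[`, numeric(1), 1))
  sessions <- sessions[ord]
  spans <- spans[ord]
  tz <- sessions[[1]]$tz_offset
  days <- vapply(spans, function(sp) session_day(sp[1], tz), character(1))
  if (length(unique(days)) > 1) {
    stop("not same day: recordings span ", paste(unique(days), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(length(sessions) - 1)) {
    if (spans[[i + 1]][1] < spans[[i]][2] - 1e-9) {
      stop("overlap: recordings ", i, " and ", i + 1, " overlap in time",
           call. = FALSE)
    }
  }

  merge_streams <- function(nm) {
    present <- Filter(Negate(is.null), lapply(sessions, `[[`, nm))
    if (length(present) == 0) return(NULL)
    out <- present[[1]]
    for (s in present[-1]) {
      prev_end <- stream_end(out)
      gaps <- rbind(out$gaps, s$gaps)
      if (s$start_unix > prev_end + 1e-9) {
        gaps <- rbind(gaps, data.frame(start = prev_end, end = s$start_unix))
      } else if (s$start_unix < prev_end - 1e-9) {
        stop("overlap: ", nm, " streams overlap in time", call. = FALSE)
      }
      out <- signal_stream(out$start_unix, out$fs,
                           rbind(out$samples, s$samples),
                           out$channel_names, out$units, gaps = gaps)
    }
    out
  }

  args <- list(source_names = unlist(lapply(sessions, `[[`, "source_names")),
               tz_offset = tz)
  for (nm in c("eda", "bvp", "hr", "temp", "acc")) args[[nm]] <- merge_streams(nm)

  ibis <- Filter(Negate(is.null), lapply(sessions, `[[`, "ibi"))
  if (length(ibis) > 0) {
    base <- min(vapply(ibis, `[[`, numeric(1), "start_unix"))
    offs <- unlist(lapply(ibis, function(r) r$beat_offsets + (r$start_unix - base)))
    ints <- unlist(lapply(ibis, `[[`, "intervals"))
    accd <- unlist(lapply(ibis, `[[`, "accepted"))
    o <- order(offs)
    args$ibi <- rr_series(base, offs[o], ints[o], accd[o])
  }
  tags <- unlist(lapply(sessions, `[[`, "tags"))
  if (!is.null(tags) && length(tags) > 0) args$tags <- sort(tags)
  do.call(e4_session, args)
}
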