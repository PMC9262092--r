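# Calendar annotations and event-marker tags, synchronized to session time.
#
# Calendars are user-written tables with columns Date (day-month-year),
# Start and End (hour:minute:second), Text and Color; events are interpreted
# in the session's display timezone, matching the workflow where the wearer
# writes down local times.

.parse_dmy <- function(x) {
  d <- as.Date(x, format = "%d-%m-%Y")
  bad <- is.na(d) | !grepl("^\\s*\\d{1,2}-\\d{1,2}-\\d{4}\\s*$", x)
  d[bad] <- NA
  d
}

.parse_hms <- function(x) {
  parts <- strsplit(trimws(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3) return(NA_real_)
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v) || v[2] >= 60 || v[3] >= 60) return(NA_real_)
    v[1] * 3600 + v[2] * 60 + v[3]
  }, numeric(1))
}

#' Read a calendar annotation table
#'
#' Accepts delimited text (tab or comma, sniffed from the header line) or a
#' spreadsheet (`.xlsx`/`.xls`, read via the readxl package when installed).
#' Requires columns Date, Start, End, Text, Color (case-insensitive). Dates
#' must be day-month-year (`dd-mm-yyyy`); times `hh:mm:ss`. Unknown color
#' names are passed through with a warning so downstream renderers can
#' decide.
#'
#' @param path Calendar file path.
#' @return Data frame of class `calendar_events`, chronologically sorted,
#'   with columns `date` (Date), `start`, `end` (seconds of day), `text`,
#'   `color`.
#' @export
read_calendar <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheets requires the readxl package; ",
           "export the calendar to CSV/TSV instead", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0) stop("bad calendar schema: empty file", call. = FALSE)
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                            colClasses = "character", strip.white = TRUE)
  }
  names(df) <- tolower(names(df))
  need <- c("date", "start", "end", "text", "color")
  if (!all(need %in% names(df))) {
    stop("bad calendar schema: need columns Date, Start, End, Text, Color",
         call. = FALSE)
  }
  df <- df[need]
  if (nrow(df) == 0) {
    out <- data.frame(date = as.Date(character(0)), start = numeric(0),
                      end = numeric(0), text = character(0),
                      color = character(0))
    class(out) <- c("calendar_events", "data.frame")
    return(out)
  }
  date <- .parse_dmy(df$date)
  start <- .parse_hms(df$start)
  end <- .parse_hms(df$end)
  for (i in seq_len(nrow(df))) {
    if (is.na(date[i])) stop("row ", i, ": unparseable date '", df$date[i],
                             "' (expected dd-mm-yyyy)", call. = FALSE)
    if (is.na(start[i]) || is.na(end[i])) {
      stop("row ", i, ": unparseable time (expected hh:mm:ss)", call. = FALSE)
    }
    if (end[i] < start[i]) {
      stop("row ", i, ": end before start", call. = FALSE)
    }
  }
  unknown <- setdiff(tolower(df$color), grDevices::colors())
  unknown <- setdiff(unknown, "")
  if (length(unknown) > 0) {
    warning("unknown color name(s) passed through: ",
            paste(unique(unknown), collapse = ", "))
  }
  out <- data.frame(date = date, start = start, end = end,
                    text = df$text, color = df$color)
  out <- out[order(out$date, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calendar_events", "data.frame")
  out
}

#' Read an event-marker tags file
#'
#' Tags are Unix times written when the wearer pressed the device button,
#' one per line.
#'
#' @param path Tags file path.
#' @param start_unix Session start, Unix seconds.
#' @return Numeric vector of event times in seconds since session start.
#'   Tags before the session start yield negative offsets and are flagged
#'   with a warning; non-numeric lines are skipped with a warning.
#' @export
read_tags <- function(path, start_unix) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(numeric(0))
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v)) {
    warning("skipped ", sum(is.na(v)), " non-numeric tag line(s)")
    v <- v[!is.na(v)]
  }
  off <- v - start_unix
  if (any(off < 0)) warning(sum(off < 0), " tag(s) precede the session start")
  off
}

# Absolute Unix start/end of a calendar event in the given display timezone.
.event_unix <- function(event_date, secs, tz_offset) {
  as.numeric(as.POSIXct(paste(format(event_date), "00:00:00"), tz = "UTC")) +
    secs - tz_offset * 60
}

#' Clip calendar events to a session
#'
#' Events are interpreted in the session's display timezone, clipped to the
#' session span; events wholly outside the session are dropped with a
#' message.
#'
#' @param session An [e4_session()].
#' @param events A `calendar_events` data frame from [read_calendar()].
#' @return Data frame with the event columns plus `rel_start`, `rel_end`
#'   (seconds since session start, clipped and non-empty).
#' @export
intersect_events <- function(session, events) {
  span <- session_span(session)
  if (nrow(events) == 0) {
    return(cbind(events, rel_start = numeric(0), rel_end = numeric(0)))
  }
  ev_start <- .event_unix(events$date, events$start, session$tz_offset)
  ev_end <- .event_unix(events$date, events$end, session$tz_offset)
  lo <- pmax(ev_start, span[1])
  hi <- pmin(ev_end, span[2])
  keep <- hi > lo
  if (any(!keep)) {
    message("dropping ", sum(!keep), " event(s) outside the session span")
  }
  out <- events[keep, , drop = FALSE]
  out$rel_start <- lo[keep] - span[1]
  out$rel_end <- hi[keep] - span[1]
  rownames(out) <- NULL
  out
}
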