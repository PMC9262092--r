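# Display aggregation and the self-contained HTML summary report.
#
# The report embeds static SVG line plots built directly by this module, so
# documents are plain text, self-contained, and byte-stable given identical
# inputs (the report timestamp is injectable for that reason).

#' Display defaults for report plots
#'
#' @param eda_range,hr_range,temp_range,movement_range Preset y-axis ranges:
#'   EDA 0-20 uS, HR 40-160 bpm, temperature 24-38 degC, movement
#'   0.98-1.25 g.
#' @param raw_plot_max Maximum session duration (s) plotted raw; longer
#'   sessions are aggregated per minute for speed.
#' @param aggregation Aggregation bin in seconds for long sessions.
#' @return A list of class `display_defaults`.
#' @export
display_defaults <- function(eda_range = c(0, 20), hr_range = c(40, 160),
                             temp_range = c(24, 38),
                             movement_range = c(0.98, 1.25),
                             raw_plot_max = 7200, aggregation = 60) {
  stopifnot(diff(eda_range) > 0, diff(hr_range) > 0, diff(temp_range) > 0,
            diff(movement_range) > 0, raw_plot_max > 0, aggregation > 0)
  structure(list(eda_range = eda_range, hr_range = hr_range,
                 temp_range = temp_range, movement_range = movement_range,
                 raw_plot_max = raw_plot_max, aggregation = aggregation),
            class = "display_defaults")
}

#' Aggregate a stream for display
#'
#' Short sessions are plotted raw; sessions longer than
#' `defaults$raw_plot_max` (2 h) are reduced to per-minute means.
#'
#' @param stream A single-channel [signal_stream()].
#' @param defaults A [display_defaults()].
#' @param session_duration Full session duration in seconds.
#' @return Data frame with `time` (s since stream start) and `value`.
#' @export
aggregate_for_display <- function(stream, defaults = display_defaults(),
                                  session_duration = stream_duration(stream)) {
  t <- stream_times(stream)
  if (length(t) == 0) return(data.frame(time = numeric(0), value = numeric(0)))
  rel <- t - t[1]
  v <- stream$samples[, 1]
  if (session_duration <= defaults$raw_plot_max) {
    return(data.frame(time = rel, value = v))
  }
  bin <- floor(rel / defaults$aggregation)
  agg <- tapply(v, bin, mean)
  data.frame(time = (as.numeric(names(agg)) + 0.5) * defaults$aggregation,
             value = as.numeric(agg))
}

# --- minimal deterministic SVG line plot ------------------------------------

.svg_num <- function(x) formatC(x, format = "f", digits = 2)

.svg_plot <- function(series, yrange, title, unit, shading = NULL,
                      vlines = NULL, refline = NULL,
                      width = 840, height = 180) {
  ml <- 50; mr <- 10; mt <- 22; mb <- 20
  pw <- width - ml - mr; ph <- height - mt - mb
  if (nrow(series) == 0) {
    return(sprintf("<svg width='%d' height='%d'><text x='10' y='20'>%s: no data</text></svg>",
                   width, height, title))
  }
  xmax <- max(series$time, 1e-9)
  sx <- function(t) ml + pw * t / xmax
  sy <- function(v) mt + ph * (1 - (pmin(pmax(v, yrange[1]), yrange[2]) - yrange[1]) /
                                 diff(yrange))
  parts <- character(0)
  parts <- c(parts, sprintf("<svg width='%d' height='%d' xmlns='http://www.w3.org/2000/svg'>",
                            width, height))
  parts <- c(parts, sprintf("<rect x='%d' y='%d' width='%d' height='%d' fill='#fafafa' stroke='#cccccc'/>",
                            ml, mt, pw, ph))
  if (!is.null(shading) && nrow(shading) > 0) {
    for (i in seq_len(nrow(shading))) {
      col <- shading$color[i]
      if (!(tolower(col) %in% grDevices::colors())) col <- "lightgray"
      parts <- c(parts, sprintf(
        "<rect x='%s' y='%d' width='%s' height='%d' fill='%s' fill-opacity='0.3'/>",
        .svg_num(sx(shading$rel_start[i])), mt,
        .svg_num(max(0.5, sx(shading$rel_end[i]) - sx(shading$rel_start[i]))),
        ph, col))
    }
  }
  if (!is.null(vlines)) {
    for (tv in vlines) {
      parts <- c(parts, sprintf(
        "<line x1='%s' y1='%d' x2='%s' y2='%d' stroke='red' stroke-width='1'/>",
        .svg_num(sx(tv)), mt, .svg_num(sx(tv)), mt + ph))
    }
  }
  if (!is.null(refline) && is.finite(refline)) {
    parts <- c(parts, sprintf(
      "<line x1='%d' y1='%s' x2='%d' y2='%s' stroke='#3366cc' stroke-dasharray='4,3'/>",
      ml, .svg_num(sy(refline)), ml + pw, .svg_num(sy(refline))))
  }
  pts <- paste(.svg_num(sx(series$time)), .svg_num(sy(series$value)),
               sep = ",", collapse = " ")
  parts <- c(parts, sprintf(
    "<polyline points='%s' fill='none' stroke='#222222' stroke-width='1'/>", pts))
  parts <- c(parts, sprintf("<text x='%d' y='14' font-size='13'>%s [%s]</text>",
                            ml, title, unit))
  parts <- c(parts, sprintf("<text x='4' y='%d' font-size='10'>%s</text>",
                            mt + 8, .svg_num(yrange[2])))
  parts <- c(parts, sprintf("<text x='4' y='%d' font-size='10'>%s</text>",
                            mt + ph, .svg_num(yrange[1])))
  parts <- c(parts, sprintf("<text x='%d' y='%d' font-size='10'>0 s</text>",
                            ml, height - 6))
  parts <- c(parts, sprintf("<text x='%d' y='%d' font-size='10' text-anchor='end'>%s s</text>",
                            ml + pw, height - 6, .svg_num(xmax)))
  parts <- c(parts, "</svg>")
  paste(parts, collapse = "\n")
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.fmt_stat <- function(x, digits = 2) {
  ifelse(is.na(x) | !is.finite(suppressWarnings(as.numeric(x))),
         "—", formatC(as.numeric(x), format = "f", digits = digits))
}

#' Render a self-contained HTML summary report
#'
#' Assembles the physiological plots (EDA, heart rate, temperature,
#' movement) with calendar shading, optional tag lines and optional
#' reference lines, the calendar table, and the summary table. Every number
#' in the summary table is copied verbatim from the supplied
#' [summarize_interval()] result; nothing is recomputed here.
#'
#' @param session An [e4_session()].
#' @param summary A `summary_row` from [summarize_interval()], or `NULL`
#'   (the summary section is then omitted with a notice).
#' @param events Optional clipped events from [intersect_events()].
#' @param tags Optional tag offsets in seconds since session start.
#' @param defaults A [display_defaults()].
#' @param options List: `title`, `show_tags` (default `TRUE`),
#'   `reference_lines` (named list per signal, value or `"mean"`),
#'   `timestamp` (report timestamp string; injectable so output is
#'   deterministic).
#' @param path Optional output file; when given the document is written
#'   there.
#' @return The HTML document as a single character string (invisibly when
#'   `path` is given).
#' @export
render_report <- function(session, summary = NULL, events = NULL,
                          tags = NULL, defaults = display_defaults(),
                          options = list(), path = NULL) {
  span <- session_span(session)
  dur <- span[2] - span[1]
  title <- options$title %||% "E4 session report"
  show_tags <- options$show_tags %||% TRUE
  stamp <- options$timestamp %||%
    format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  reflines <- options$reference_lines %||% list()

  shading <- if (!is.null(events) && nrow(events) > 0) events else NULL
  vlines <- if (isTRUE(show_tags) && !is.null(tags) && length(tags) > 0) tags else NULL

  plot_block <- function(nm, title_txt, unit, range) {
    s <- session[[nm]]
    if (is.null(s) || n_samples(s) == 0) return("")
    series <- aggregate_for_display(s, defaults, dur)
    rl <- reflines[[nm]]
    if (identical(rl, "mean")) rl <- mean(series$value)
    .svg_plot(series, range, title_txt, unit, shading = shading,
              vlines = vlines, refline = rl)
  }

  mag_block <- function() {
    if (is.null(session$acc) || n_samples(session$acc) == 0) return("")
    mag <- acc_mean_magnitude(session$acc)
    series <- aggregate_for_display(mag, defaults, dur)
    rl <- reflines[["movement"]]
    if (identical(rl, "mean")) rl <- mean(series$value)
    .svg_plot(series, defaults$movement_range, "Movement", "g",
              shading = shading, vlines = vlines, refline = rl)
  }

  cal_table <- if (!is.null(events) && nrow(events) > 0) {
    rows <- vapply(seq_len(nrow(events)), function(i) {
      sprintf("<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
              format(events$date[i]),
              .fmt_stat(events$rel_start[i], 0),
              .fmt_stat(events$rel_end[i], 0),
              .html_escape(events$text[i]),
              .html_escape(events$color[i]))
    }, character(1))
    paste0("<h2>Calendar</h2><table><tr><th>Date</th><th>Start (s)</th>",
           "<th>End (s)</th><th>Text</th><th>Color</th></tr>",
           paste(rows, collapse = ""), "</table>")
  } else "<h2>Calendar</h2><p>No calendar events supplied.</p>"

  sum_table <- if (is.null(summary)) {
    "<h2>Summary</h2><p>No analysis summary supplied; section omitted.</p>"
  } else {
    paste0(
      "<h2>Summary</h2><table>",
      "<tr><th>Measure</th><th>Value</th></tr>",
      sprintf("<tr><td>Mean EDA (uS)</td><td>%s</td></tr>", .fmt_stat(summary$mean_eda, 3)),
      sprintf("<tr><td>SCR peaks per minute</td><td>%s</td></tr>", .fmt_stat(summary$peaks_per_min, 2)),
      sprintf("<tr><td>Mean HR (bpm)</td><td>%s</td></tr>", .fmt_stat(summary$mean_hr, 1)),
      sprintf("<tr><td>RMSSD (ms)</td><td>%s</td></tr>", .fmt_stat(summary$rmssd, 1)),
      sprintf("<tr><td>Mean temperature (degC)</td><td>%s</td></tr>", .fmt_stat(summary$mean_temp, 2)),
      sprintf("<tr><td>Mean movement (g)</td><td>%s</td></tr>", .fmt_stat(summary$mean_movement, 3)),
      sprintf("<tr><td>EDA artifact fraction</td><td>%s%%</td></tr>",
              .fmt_stat(100 * summary$eda_artifact_fraction, 1)),
      sprintf("<tr><td>Beat acceptance fraction</td><td>%s%%</td></tr>",
              .fmt_stat(100 * summary$beat_acceptance_fraction, 1)),
      if (isTRUE(summary$movement_present)) {
        "<tr><td colspan='2'><em>High movement present: interpret HRV with caution.</em></td></tr>"
      } else "",
      "</table>")
  }

  html <- paste(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'/>",
    sprintf("<title>%s</title>", .html_escape(title)),
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;}",
    "td,th{border:1px solid #999;padding:4px 8px;}h1{font-size:1.4em;}</style>",
    "</head><body>",
    sprintf("<h1>%s</h1>", .html_escape(title)),
    sprintf("<p>Session %s, start %s, duration %.1f min. Generated %s.</p>",
            .html_escape(paste(session$source_names, collapse = " + ")),
            format_session_time(span[1], session$tz_offset), dur / 60,
            .html_escape(stamp)),
    plot_block("eda", "EDA", "uS", defaults$eda_range),
    plot_block("hr", "Heart rate", "bpm", defaults$hr_range),
    plot_block("temp", "Temperature", "degC", defaults$temp_range),
    mag_block(),
    cal_table,
    sum_table,
    "</body></html>",
    sep = "\n")
  if (!is.null(path)) {
    writeLines(html, path)
    return(invisible(html))
  }
  html
}
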