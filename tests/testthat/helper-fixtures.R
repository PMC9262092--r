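# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

eda_csv_lines <- function(start = 1581000000, fs = 4, values = numeric(0)) {
  c(format(start, scientific = FALSE), format(fs), as.character(values))
}

# A small all-stream session with a couple of SCRs and a clean RR series.
small_spec <- function(duration = 60, seed = 7, ...) {
  synth_spec(
    duration = duration, seed = seed,
    scr_events = data.frame(time = c(10, 35), amplitude = c(0.5, 0.3),
                            rise = c(2, 2), decay = c(4, 4)),
    ...)
}

# A randomized spec for property-style loops (seeded by the caller).
random_spec <- function(seed, duration = NULL) {
  if (is.null(duration)) duration <- sample(15:30, 1)
  n_scr <- sample(0:2, 1)
  events <- if (n_scr > 0) {
    data.frame(time = seq(5, by = 12, length.out = n_scr),
               amplitude = runif(n_scr, 0.05, 0.6),
               rise = rep(1.5, n_scr), decay = rep(3, n_scr))
  } else NULL
  synth_spec(duration = duration, seed = seed, scr_events = events,
             mean_hr = runif(1, 55, 90),
             tags = if (runif(1) > 0.5) c(2, duration / 2) else NULL)
}

expect_streams_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$start_unix, b$start_unix, tolerance = 1e-9)
  expect_equal(a$fs, b$fs)
  expect_equal(dim(a$samples), dim(b$samples))
  if (length(a$samples) > 0) {
    expect_lt(max(abs(a$samples - b$samples)), tol)
  }
}

expect_sessions_equal <- function(a, b, tol = 1e-6) {
  for (nm in c("eda", "bvp", "hr", "temp", "acc")) {
    expect_identical(is.null(a[[nm]]), is.null(b[[nm]]))
    if (!is.null(a[[nm]])) expect_streams_equal(a[[nm]], b[[nm]], tol)
  }
  expect_identical(is.null(a$ibi), is.null(b$ibi))
  if (!is.null(a$ibi)) {
    expect_equal(a$ibi$start_unix, b$ibi$start_unix, tolerance = 1e-9)
    expect_equal(a$ibi$beat_offsets, b$ibi$beat_offsets, tolerance = 1e-6)
    expect_equal(a$ibi$intervals, b$ibi$intervals, tolerance = 1e-6)
  }
}
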