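# E4 dialect parsing, archive round trips, same-day merging.

test_that("signal CSV header rows give start time, frequency, and timing", {
  s <- parse_signal_csv(eda_csv_lines(1581000000, 4, c(1:8) / 10))
  expect_equal(s$start_unix, 1581000000)
  expect_equal(s$fs, 4)
  expect_equal(n_samples(s), 8L)
  expect_equal(stream_duration(s), 2) # 8 rows of 250 ms
  t <- stream_times(s)
  # sample index 3 (0-based) sits at start + 0.75 s
  expect_equal(t[4] - s$start_unix, 0.75)
  expect_equal(t[8] - t[1], (8 - 1) / 4)
})

test_that("multi-channel files parse with repeated header columns", {
  lines <- c("1581000000,1581000000,1581000000", "32,32,32",
             "1,2,3", "4,5,6")
  s <- parse_signal_csv(lines, n_channels = 3, channel_names = c("x", "y", "z"))
  expect_equal(s$fs, 32)
  expect_equal(ncol(s$samples), 3L)
  expect_equal(s$samples[2, ], c(x = 4, y = 5, z = 6))
})

test_that("empty payload gives a valid zero-sample stream", {
  s <- parse_signal_csv(eda_csv_lines(values = numeric(0)))
  expect_equal(n_samples(s), 0L)
})

test_that("malformed signal CSVs are rejected as bad dialect", {
  expect_error(parse_signal_csv(c("abc", "4", "1")), "bad dialect")
  expect_error(parse_signal_csv(c("1581000000", "0", "1")), "bad dialect")
  expect_error(parse_signal_csv(c("1581000000", "-4", "1")), "bad dialect")
  expect_error(parse_signal_csv(c("1581000000", "4", "1", "x")), "bad dialect")
})

test_that("IBI parsing handles beats, device gaps, labels, and empties", {
  s <- parse_ibi_csv(c("1581000000,IBI", "10.0,1.0", "11.0,1.0"))
  expect_equal(s$beat_offsets, c(10, 11))
  expect_equal(s$intervals, c(1, 1))
  expect_true(all(s$accepted))

  gap <- parse_ibi_csv(c("1581000000,IBI", "10.0,1.0", "14.0,0.9"))
  expect_equal(n_beats(gap), 2L) # device-discarded beats leave a gap

  expect_equal(n_beats(parse_ibi_csv("1581000000,IBI")), 0L)
  expect_error(parse_ibi_csv(c("0,IBI", "10,1", "9,1")), "non-monotone")
  expect_error(parse_ibi_csv(c("0,IBI", "10,0")), "bad interval")
})

test_that("a minimal archive with only EDA.csv reads as an EDA-only session", {
  tmp <- tempfile(fileext = ".zip")
  e4tools:::zip_write(tmp, list("EDA.csv" = eda_csv_lines(values = rep(2, 8))))
  s <- read_session(tmp)
  expect_s3_class(s$eda, "signal_stream")
  for (nm in c("bvp", "hr", "temp", "acc")) expect_null(s[[nm]])
  expect_null(s$ibi)
})

test_that("write then read is the identity on synthetic sessions", {
  built <- synth_session(small_spec(tags = NULL))
  tmp <- tempfile(fileext = ".zip")
  write_session(built$session, tmp)
  back <- read_session(tmp)
  expect_sessions_equal(built$session, back)
})

test_that("sessions without IBI omit IBI.csv; tags round-trip", {
  built <- synth_session(small_spec())
  ses <- built$session
  ses$ibi <- NULL
  ses$tags <- ses$eda$start_unix + c(5, 20)
  tmp <- tempfile(fileext = ".zip")
  write_session(ses, tmp)
  members <- utils::unzip(tmp, list = TRUE)$Name
  expect_false("IBI.csv" %in% members)
  expect_true("tags.csv" %in% members)
  back <- read_session(tmp)
  expect_equal(back$tags, ses$tags)
})

test_that("unreadable or missing archives raise clear errors", {
  expect_error(read_session(tempfile(fileext = ".zip")), "unreadable archive")
  bad <- tempfile(fileext = ".zip")
  writeBin(as.raw(1:10), bad)
  expect_error(read_session(bad), "unreadable archive")
})

test_that("IBI re-serialization preserves offsets and intervals to 6 decimals", {
  set.seed(11)
  off <- cumsum(runif(25, 0.7, 1.3))
  int <- runif(25, 0.7, 1.3)
  txt <- e4tools:::.serialize_ibi_csv(rr_series(1581000000, off, int))
  back <- parse_ibi_csv(txt)
  expect_equal(back$beat_offsets, round(off, 6), tolerance = 1e-9)
  expect_equal(back$intervals, round(int, 6), tolerance = 1e-9)
})

test_that("same-day merging preserves the gap and is order-insensitive", {
  s1 <- synth_session(synth_spec(duration = 30, seed = 1,
                                 start_unix = 1581000000))$session
  s2 <- synth_session(synth_spec(duration = 30, seed = 2,
                                 start_unix = 1581003630))$session # +1h gap
  m12 <- merge_same_day(list(s1, s2))
  m21 <- merge_same_day(list(s2, s1))
  expect_sessions_equal(m12, m21)
  expect_equal(m12$eda$start_unix, s1$eda$start_unix)
  span <- session_span(m12)
  expect_equal(span[2] - span[1], 3660, tolerance = 1)
  expect_gt(nrow(m12$eda$gaps), 0) # the hour off-wrist is a recorded gap
  # no fabricated samples: counts add up
  expect_equal(n_samples(m12$eda), n_samples(s1$eda) + n_samples(s2$eda))
  # IBI offsets rebased to the merged start
  expect_equal(m12$ibi$start_unix, s1$ibi$start_unix)
  expect_true(all(diff(m12$ibi$beat_offsets) > 0))
  # single session returned unchanged
  expect_identical(merge_same_day(list(s1)), s1)
})

test_that("merging rejects overlap and different days", {
  s1 <- synth_session(synth_spec(duration = 60, seed = 1,
                                 start_unix = 1581000000))$session
  s2 <- synth_session(synth_spec(duration = 60, seed = 2,
                                 start_unix = 1581000030))$session
  expect_error(merge_same_day(list(s1, s2)), "overlap")
  s3 <- synth_session(synth_spec(duration = 60, seed = 3,
                                 start_unix = 1581000000 + 86400 * 2))$session
  expect_error(merge_same_day(list(s1, s3)), "not same day")
})

test_that("a session merged from two recordings epochs across the gap safely", {
  s1 <- synth_session(synth_spec(duration = 30, seed = 1,
                                 start_unix = 1581000000))$session
  s2 <- synth_session(synth_spec(duration = 30, seed = 2,
                                 start_unix = 1581000100))$session
  m <- merge_same_day(list(s1, s2))
  proc <- preprocess_eda(m$eda)
  feats <- epoch_eda_features(proc)
  # only epochs fully inside a contiguous segment survive: 6 per 30-s piece
  expect_lte(nrow(feats), 12)
  expect_gte(nrow(feats), 10)
})
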