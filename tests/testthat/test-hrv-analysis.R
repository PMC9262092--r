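# RR plausibility filtering, heart-rate series, time/frequency-domain HRV.

test_that("plausibility bounds derive from the configured heart-rate range", {
  cfg <- rr_filter_config()
  expect_equal(rr_max_interval(cfg), 1.5)                      # 60/40 bpm
  expect_equal(rr_max_interval(cfg, allow_missed = TRUE), 3)   # one missed beat
  expect_equal(rr_ratio_bound(cfg), 1.1)
  expect_equal(rr_ratio_bound(cfg, allow_missed = TRUE), 2.2)
  expect_equal(bpm_to_hz(40), 2 / 3)
  expect_equal(bpm_to_hz(180), 3)
})

test_that("a regular 60-bpm series is fully accepted", {
  s <- rr_series(0, 1:120, rep(1, 120))
  r <- filter_rr(s)
  expect_equal(r$n_accepted, r$n_original)
  expect_equal(r$n_accepted / r$n_original, 1.0)
})

test_that("an implausibly long interval amid regular beats is rejected", {
  int <- rep(1, 30); int[15] <- 2.0 # 30 bpm with no missed-beat context
  s <- rr_series(0, cumsum(int), int)
  r <- filter_rr(s)
  expect_false(r$series$accepted[15])
  expect_equal(sum(!r$series$accepted), 1L)
})

test_that("too-short intervals are rejected outright", {
  int <- rep(1, 20); int[10] <- 0.2 # 300 bpm, below 60/180 s
  s <- rr_series(0, cumsum(int), int)
  r <- filter_rr(s)
  expect_false(r$series$accepted[10])
})

test_that("disabling the missed-beat allowance rejects every 2-s interval", {
  cfg <- rr_filter_config(missed_beat_factor = 1)
  int <- rep(1, 40); int[c(10, 25)] <- 2.0
  s <- rr_series(0, cumsum(int), int)
  r <- filter_rr(s, cfg)
  expect_false(any(r$series$accepted[c(10, 25)]))
  expect_true(all(r$series$accepted[-c(10, 25)]))
})

test_that("clean jittered series pass; the filter is idempotent", {
  spec <- synth_spec(duration = 300, seed = 21, mean_hr = 60, hr_jitter_sd = 20)
  s <- synth_rr_series(spec)$series
  r1 <- filter_rr(s)
  expect_equal(r1$n_accepted / r1$n_original, 1.0)
  # idempotence over randomized series with anomalies
  for (seed in 1:5) {
    spec <- synth_spec(duration = 120, seed = seed, mean_hr = 72,
                       hr_jitter_sd = 30,
                       rr_anomalies = data.frame(index = c(20, 60),
                                                 kind = c("missed", "ectopic_short")))
    s <- synth_rr_series(spec)$series
    r1 <- filter_rr(s)
    r2 <- filter_rr(r1$series)
    expect_identical(r1$series$accepted, r2$series$accepted)
  }
})

test_that("the interpolated heart-rate series hits forced endpoints", {
  s <- rr_series(0, 1:60, rep(1, 60))
  hr <- rr_to_hr_series(s, fs = 4)
  expect_true(all(abs(hr$samples - 60) < 1e-9))

  s2 <- rr_series(0, c(1, 1.5), c(1, 0.5))
  hr2 <- rr_to_hr_series(s2, fs = 4)
  expect_equal(as.numeric(hr2$samples[1, 1]), 60)
  expect_equal(as.numeric(hr2$samples[nrow(hr2$samples), 1]), 120)
  expect_true(all(diff(hr2$samples[, 1]) >= 0))

  s3 <- rr_series(0, 0:300, c(1, rep(1, 300)))
  expect_equal(n_samples(rr_to_hr_series(s3, fs = 4)), 1 + 300 * 4)

  one <- rr_series(0, 1, 1)
  expect_error(rr_to_hr_series(one), "insufficient beats")
})

test_that("time-domain measures match hand computations", {
  r1 <- hrv_time_domain(rr_series(0, 1:3, c(1, 1, 1)))
  expect_equal(r1$rmssd, 0)
  expect_equal(r1$sdnn, 0)
  expect_equal(r1$mean_hr, 60)
  expect_equal(r1$pnn50, 0)

  r2 <- hrv_time_domain(rr_series(0, c(1, 2), c(0.8, 1.0)))
  expect_equal(r2$rmssd, 200)

  r3 <- hrv_time_domain(rr_series(0, 1:3, c(1.0, 1.04, 1.0)))
  expect_equal(r3$pnn50, 0) # both diffs are 40 ms, under the 50 ms bar
  r4 <- hrv_time_domain(rr_series(0, 1:3, c(1.0, 1.06, 1.0)))
  expect_equal(r4$pnn50, 100)
})

test_that("rmssd and sdnn match a brute-force oracle on random series", {
  brute <- function(rr) {
    n <- length(rr)
    m <- sum(rr) / n
    sdnn <- sqrt(sum((rr - m)^2) / (n - 1)) * 1000
    ss <- 0
    for (i in 2:n) ss <- ss + (rr[i] - rr[i - 1])^2
    list(sdnn = sdnn, rmssd = sqrt(ss / (n - 1)) * 1000)
  }
  set.seed(31)
  for (i in 1:50) {
    rr <- runif(sample(2:20, 1), 0.5, 1.5)
    got <- hrv_time_domain(rr_series(0, cumsum(rr), rr))
    want <- brute(rr)
    expect_equal(got$sdnn, want$sdnn, tolerance = 1e-12)
    expect_equal(got$rmssd, want$rmssd, tolerance = 1e-12)
  }
})

test_that("hrv on filtered series uses accepted beats only", {
  int <- rep(1, 30); int[15] <- 2.5
  s <- rr_series(0, cumsum(int), int)
  r <- filter_rr(s)
  td <- hrv_time_domain(r$series)
  expect_equal(td$sdnn, 0) # the outlier was rejected
})

test_that("a constant tachogram has (numerically) zero band power", {
  hr <- signal_stream(0, 4, rep(60, 4 * 300), "hr", "bpm")
  fd <- hrv_frequency_domain(hr)
  expect_lt(fd$lf_power, 1e-12)
  expect_lt(fd$hf_power, 1e-12)
})

test_that("band powers localize pure LF and HF modulations", {
  fs <- 4
  t <- seq(0, 300, by = 1 / fs)
  rr_lf <- 1.0 + 0.05 * sin(2 * pi * 0.1 * t)  # 0.1 Hz -> LF band
  hr_lf <- signal_stream(0, fs, 60 / rr_lf, "hr", "bpm")
  fd_lf <- hrv_frequency_domain(hr_lf)
  expect_gt(fd_lf$lf_power / fd_lf$total_power, 0.95)

  rr_hf <- 1.0 + 0.05 * sin(2 * pi * 0.25 * t) # 0.25 Hz -> HF band
  hr_hf <- signal_stream(0, fs, 60 / rr_hf, "hr", "bpm")
  fd_hf <- hrv_frequency_domain(hr_hf)
  expect_gt(fd_hf$hf_power / fd_hf$total_power, 0.95)
  expect_lt(fd_hf$lf_hf_ratio, 0.1)
})

test_that("total spectral power matches the tachogram variance (Parseval)", {
  spec <- synth_spec(duration = 900, seed = 41, mean_hr = 65, hr_jitter_sd = 40)
  s <- synth_rr_series(spec)$series
  hr <- rr_to_hr_series(filter_rr(s)$series, fs = 4)
  rr_ms <- 60000 / hr$samples[, 1]
  fd <- hrv_frequency_domain(hr)
  expect_equal(fd$total_power, stats::var(rr_ms), tolerance = 0.05)
})

test_that("short series are refused for spectral analysis", {
  hr <- signal_stream(0, 4, rep(60, 4 * 30), "hr", "bpm")
  expect_error(hrv_frequency_domain(hr), "insufficient duration")
})
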