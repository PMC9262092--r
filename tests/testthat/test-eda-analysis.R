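# EDA preprocessing, validity rules, epoch features, artifact labels, peaks.

test_that("preprocessing upsamples 4 Hz input to an 8 Hz stream", {
  s <- signal_stream(1581000000, 4, rep(2, 240), "eda", "uS") # 60 s
  p <- preprocess_eda(s)
  expect_equal(p$fs, 8)
  expect_equal(n_samples(p), 480L)
  expect_equal(stream_duration(p), 60)
})

test_that("a constant signal passes through the low-pass unchanged", {
  s <- signal_stream(0, 4, rep(2, 240), "eda", "uS")
  p <- preprocess_eda(s)
  expect_lt(max(abs(p$samples - 2)), 1e-6)
})

test_that("near-Nyquist content is strongly attenuated", {
  fs <- 4
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 2 + 0.5 * sin(2 * pi * 1.9 * t) # 1.9 Hz on a 4 Hz stream
  p <- preprocess_eda(signal_stream(0, fs, x, "eda", "uS"))
  # amplitude of the residual oscillation, mid-stream to avoid edges
  mid <- p$samples[100:380, 1]
  atten <- (max(mid) - min(mid)) / 2 / 0.5
  expect_lt(20 * log10(atten), -20)
})

test_that("preprocessing refuses to downsample and passes empties through", {
  s <- signal_stream(0, 16, rep(1, 32), "eda", "uS")
  expect_error(preprocess_eda(s), "downsampling unsupported")
  e <- signal_stream(0, 4, numeric(0), "eda", "uS")
  expect_equal(n_samples(preprocess_eda(e)), 0L)
})

test_that("validity rules discard values outside the device range", {
  s <- signal_stream(0, 8, c(0.005, 5, 150, 0.01, 100), "eda", "uS")
  expect_equal(apply_validity_rules(s), c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("epoch count is floor(duration / epoch_len)", {
  mk <- function(secs) signal_stream(0, 8, rep(2, secs * 8), "eda", "uS")
  expect_equal(nrow(epoch_eda_features(mk(60))), 12L)
  expect_equal(nrow(epoch_eda_features(mk(59))), 11L)
  expect_equal(nrow(epoch_eda_features(mk(4))), 0L)
})

test_that("difference-based features vanish on a constant stream", {
  f <- epoch_eda_features(signal_stream(0, 8, rep(3, 80), "eda", "uS"))
  expect_true(all(f$max_abs_d1 == 0))
  expect_true(all(f$max_abs_d2 == 0))
  expect_true(all(f$w1_max == 0))
  expect_true(all(f$w05_max == 0))
})

test_that("default rules label clean signals clean and step injections artifact", {
  clean <- epoch_eda_features(signal_stream(0, 8, rep(2, 480), "eda", "uS"))
  lab <- classify_eda_artifacts(clean)
  expect_true(all(lab$label == "clean"))

  spec <- synth_spec(duration = 60, seed = 3, eda_noise_sd = 0.001,
                     artifact_epochs = data.frame(epoch = 3, kind = "step"))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  lab2 <- classify_eda_artifacts(epoch_eda_features(proc))
  expect_equal(lab2$label[lab2$epoch_index == 3], "artifact")
})

test_that("binary mode never emits unclear; ternary may", {
  spec <- synth_spec(duration = 60, seed = 4,
                     artifact_epochs = data.frame(epoch = c(2, 7),
                                                  kind = c("spike", "step")))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  f <- epoch_eda_features(proc)
  lab_bin <- classify_eda_artifacts(f, eda_config(classifier_mode = "binary"))
  expect_true(all(lab_bin$label %in% c("clean", "artifact")))
  lab_ter <- classify_eda_artifacts(f, eda_config(classifier_mode = "ternary"))
  expect_true(all(lab_ter$label %in% c("clean", "unclear", "artifact")))
})

test_that("a pluggable linear model drives labels; mismatches error", {
  f <- epoch_eda_features(signal_stream(0, 8, rep(2, 480), "eda", "uS"))
  always_artifact <- list(weights = c(mean = 0), bias = 1)
  lab <- classify_eda_artifacts(f, model = always_artifact)
  expect_true(all(lab$label == "artifact"))
  bad <- list(weights = c(nonexistent_feature = 1), bias = 0)
  expect_error(classify_eda_artifacts(f, model = bad), "model mismatch")
})

test_that("a flat signal yields no peaks", {
  p <- detect_scr_peaks(preprocess_eda(signal_stream(0, 4, rep(2, 240), "eda", "uS")))
  expect_equal(nrow(p), 0L)
})

test_that("a single synthetic SCR yields one peak with the expected features", {
  spec <- synth_spec(duration = 60, seed = 5, eda_noise_sd = 0,
                     scr_events = data.frame(time = 20, amplitude = 0.5,
                                             rise = 2, decay = 4))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  pk <- detect_scr_peaks(proc)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$amplitude, 0.5, tolerance = 0.05)
  # smoothing widens the trough-to-apex rise by up to the filter support
  expect_equal(pk$rise_time, 2, tolerance = 0.4)
  expect_equal(pk$max_derivative, 0.25, tolerance = 0.15)
  expect_equal(pk$rise_time, pk$apex_time - pk$start_time)
  expect_gt(pk$max_derivative, 0)
  expect_false(is.na(pk$decay_time))
  expect_false(is.na(pk$width))
  expect_gt(pk$auc, 0)
  expect_equal(pk$half_recovery_time - pk$apex_time, pk$decay_time)
})

test_that("the amplitude threshold separates 0.004 from 0.010 uS events", {
  spec <- synth_spec(duration = 80, seed = 6, eda_noise_sd = 0,
                     scr_events = data.frame(time = c(15, 50),
                                             amplitude = c(0.004, 0.010),
                                             rise = c(2, 2), decay = c(4, 4)))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  pk <- detect_scr_peaks(proc)
  expect_equal(nrow(pk), 1L)
  expect_gt(pk$amplitude, 0.005)
  expect_lt(abs(pk$start_time - proc$start_unix - 50), 3)
})

test_that("peaks inside artifact epochs or invalid samples are excluded", {
  spec <- synth_spec(duration = 60, seed = 8, eda_noise_sd = 0,
                     scr_events = data.frame(time = 17, amplitude = 0.5,
                                             rise = 2, decay = 4))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  # label the epoch containing the rise as artifact
  labels <- data.frame(epoch_index = 3, t_start = proc$start_unix + 15,
                       label = "artifact")
  expect_equal(nrow(detect_scr_peaks(proc, labels = labels)), 0L)

  # dropout to near zero makes samples invalid, excluding the peak
  low <- proc
  low$samples[, 1] <- low$samples[, 1] - 1.995 # baseline 2 -> 0.005 < valid_min
  expect_equal(nrow(detect_scr_peaks(low)), 0L)
})

test_that("constant offsets shift eda_at_start but not detection or labels", {
  spec <- synth_spec(duration = 60, seed = 9,
                     scr_events = data.frame(time = 20, amplitude = 0.4,
                                             rise = 2, decay = 4))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  shifted <- proc
  shifted$samples <- shifted$samples + 3
  f1 <- epoch_eda_features(proc); f2 <- epoch_eda_features(shifted)
  expect_equal(classify_eda_artifacts(f1)$label, classify_eda_artifacts(f2)$label)
  p1 <- detect_scr_peaks(proc); p2 <- detect_scr_peaks(shifted)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p2$eda_at_start, p1$eda_at_start + 3, tolerance = 1e-9)
  expect_equal(p2$amplitude, p1$amplitude, tolerance = 1e-9)
})

test_that("an always-clean classifier reduces to unmasked peak detection", {
  spec <- synth_spec(duration = 90, seed = 10,
                     scr_events = data.frame(time = c(15, 45, 70),
                                             amplitude = c(0.3, 0.5, 0.2),
                                             rise = c(2, 2, 2), decay = c(4, 4, 4)))
  proc <- preprocess_eda(synth_scr_train(spec)$stream)
  f <- epoch_eda_features(proc)
  always_clean <- list(weights = c(mean = 0), bias = -1)
  lab <- classify_eda_artifacts(f, model = always_clean)
  expect_equal(detect_scr_peaks(proc, labels = lab), detect_scr_peaks(proc))
})

test_that("every reported peak clears the amplitude threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    spec <- random_spec(seed, duration = 30)
    proc <- preprocess_eda(synth_scr_train(spec)$stream)
    pk <- detect_scr_peaks(proc)
    if (nrow(pk) > 0) {
      expect_true(all(pk$amplitude >= 0.005))
      expect_true(all(pk$apex_time > pk$start_time))
      expect_true(all(pk$max_derivative > 0))
    }
  }
})

test_that("peaks-per-minute is count over analyzable minutes", {
  pk6 <- data.frame(x = 1:6)
  expect_equal(peaks_per_minute(pk6, 180), 2)
  expect_equal(peaks_per_minute(pk6[0, , drop = FALSE], 60), 0)
  expect_equal(peaks_per_minute(data.frame(x = 1:10), 600), 1)
  expect_error(peaks_per_minute(pk6, 0), "no analyzable data")
})
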