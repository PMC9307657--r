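test_that("EEG band-pass meets printed ripple and attenuation specs", {
  fspec <- design_filter("C3-M2")
  expect_equal(fspec$order, 16)
  expect_equal(fspec$cutoffs_hz, c(0.3, 45))
  H <- abs(sos_freqz(fspec$sos, seq(0.35, 44.9, length.out = 5000), 128))
  dev_db <- 20 * log10(H)
  expect_lte(max(dev_db), 1e-6)
  expect_gte(min(dev_db), -1 - 1e-6)
  Hs <- abs(sos_freqz(fspec$sos, c(seq(0.01, 0.25, length.out = 2000),
                                   seq(47, 63.9, length.out = 2000)), 128))
  expect_gte(min(-20 * log10(Hs)), 40 - 1e-6)
})

test_that("per-role filter table matches the standardized prefilters", {
  expect_equal(design_filter("L-EOG")$cutoffs_hz, c(0.3, 45))
  expect_equal(design_filter("chinEMG")$type, "highpass")
  expect_equal(design_filter("chinEMG")$cutoffs_hz, 10)
  expect_equal(design_filter("ECG")$cutoffs_hz, 0.3)
  expect_equal(design_filter("nasal_pressure")$cutoffs_hz, 0.1)
  expect_equal(design_filter("airflow")$cutoffs_hz, c(0.1, 15))
  expect_equal(design_filter("SaO2")$type, "none")
  expect_error(design_filter("bogus"), class = "somnoage_filter_error")
})

test_that("zero-phase filtering leaves a symmetric pulse symmetric", {
  fspec <- design_filter("C3-M2")
  n <- 4096
  x <- exp(-0.5 * ((seq_len(n) - n / 2) / 40)^2)   # Gaussian pulse
  y <- apply_filter(signal_trace("C3-M2", x, 128), fspec)$samples
  expect_equal(which.max(y), n / 2)
  # cross-correlation peak lag between band-limited input and output is 0
  set.seed(2)
  xb <- sos_filtfilt(ellip_sos(4, 1, 40, c(2, 20) / 64, "pass"), rnorm(n))
  yb <- apply_filter(signal_trace("C3-M2", xb, 128), fspec)$samples
  cc <- ccf(yb, xb, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stopband tone is suppressed at least 40 dB below an in-band tone", {
  fspec <- design_filter("C3-M2")
  t <- (0:16383) / 128
  inband <- sin(2 * pi * 10 * t)
  stopt <- sin(2 * pi * 60 * t)
  y_in <- apply_filter(signal_trace("C3-M2", inband, 128), fspec)$samples
  y_st <- apply_filter(signal_trace("C3-M2", stopt, 128), fspec)$samples
  mid <- 2000:14000
  ratio_db <- 10 * log10(mean(y_st[mid]^2) / mean(y_in[mid]^2))
  expect_lte(ratio_db, -40)
})

test_that("SaO2 passes through filtering untouched", {
  tr <- signal_trace("SaO2", c(95, 96, 97, 94), 128, "%")
  expect_identical(apply_filter(tr, design_filter("SaO2"))$samples, tr$samples)
})

test_that("resampler preserves tones and durations", {
  t <- (0:2559) / 256
  out <- resample_trace(signal_trace("C3-M2", sin(2 * pi * 10 * t), 256), 128)
  expect_equal(out$fs, 128)
  expect_length(out$samples, 1280)
  amp <- 2 * Mod(fft(out$samples)) / length(out$samples)
  f_axis <- (seq_along(out$samples) - 1) * 128 / length(out$samples)
  expect_equal(f_axis[which.max(amp)], 10)
  expect_lt(abs(max(amp) - 1), 0.01)

  # SaO2 goes through linear interpolation
  sa <- resample_trace(signal_trace("SaO2", c(90, 92), 1, "%"), 128)
  expect_equal(sa$samples[65], 91)

  # already at target: identity
  tr <- test_trace(n = 256, fs = 128)
  expect_identical(resample_trace(tr, 128)$samples, tr$samples)

  expect_error(resample_trace(signal_trace("C3-M2", c(1, 2, 3), 0.5), 128),
               class = "somnoage_resample_error")
})

test_that("amplitude normalization anchors the 5th/95th percentiles", {
  set.seed(3)
  x <- rnorm(10000, sd = 30)
  tr <- normalize_amplitude(signal_trace("C3-M2", x, 128))
  p <- quantile(x, c(0.05, 0.95), names = FALSE)
  i95 <- which.min(abs(x - p[2]))
  expect_equal(tr$samples[i95], 2 * (x[i95] - p[1]) / (p[2] - p[1]) - 1,
               tolerance = 1e-12)
  # a sample exactly at the 95th percentile maps to +1
  x2 <- seq(0, 100, length.out = 101)    # p95 = 95 is a data point
  tr2 <- normalize_amplitude(signal_trace("C3-M2", x2, 128))
  expect_equal(tr2$samples[96], 1, tolerance = 1e-12)
  # symmetric percentiles map the midpoint to 0
  xs <- seq(-50, 50, length.out = 1001)
  trs <- normalize_amplitude(signal_trace("C3-M2", xs, 128))
  expect_equal(trs$samples[501], 0, tolerance = 1e-12)
  # constant trace: zeros plus the degeneracy flag
  trc <- normalize_amplitude(signal_trace("C3-M2", rep(5, 100), 128))
  expect_true(all(trc$samples == 0))
  expect_true(isTRUE(attr(trc, "degenerate")))
})

test_that("normalization is idempotent up to the affine re-fit", {
  set.seed(9)
  tr <- normalize_amplitude(signal_trace("C3-M2", rnorm(5000), 128))
  tr2 <- normalize_amplitude(tr)
  # re-normalizing an already-anchored trace is the identity
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-10)
})

test_that("SaO2 normalization uses the fixed 60/100 anchors", {
  tr <- normalize_sao2(signal_trace("SaO2", c(100, 80, 60), 1, "%"))
  expect_equal(tr$samples, c(1, 0, -1))
  trc <- normalize_sao2(signal_trace("SaO2", c(-5, 90), 1, "%"))
  expect_equal(trc$samples[1], (0 - 80) / 20)
  expect_equal(attr(trc, "clipped"), 1)
})

test_that("assemble stacks, zero-substitutes and applies the missing rule", {
  meta <- subject_meta("as1", age = 50)
  spec_d <- channel_set_spec("d")
  mk <- function(lab, n = 100) signal_trace(lab, rnorm(n), 128)
  set.seed(10)
  traces <- list(airflow = mk("airflow"), nasal_pressure = mk("nasal_pressure"),
                 thor_belt = mk("thor_belt"), abd_belt = mk("abd_belt"),
                 SaO2 = missing_trace("SaO2"))
  pre <- assemble(traces, spec_d, meta)
  expect_false(pre$excluded)
  expect_equal(pre$mask, c(0L, 0L, 0L, 0L, 1L))
  expect_true(all(pre$x[5, ] == 0))
  expect_equal(rownames(pre$x), spec_d$channels)

  # two missing signals anywhere in the montage: record excluded
  traces2 <- traces
  traces2$abd_belt <- missing_trace("abd_belt")
  pre2 <- assemble(traces2, spec_d, meta)
  expect_true(pre2$excluded)
  expect_equal(pre2$exclude_reason, "gt1_signal_missing")
  expect_null(pre2$x)

  # all present: order matches the channel-set order exactly
  traces3 <- traces; traces3$SaO2 <- mk("SaO2")
  pre3 <- assemble(traces3, spec_d, meta)
  expect_equal(rownames(pre3$x), spec_d$channels)
  expect_equal(pre3$mask, rep(0L, 5))

  # length trim to the shortest channel; > 1 s discrepancy excludes
  traces4 <- traces3; traces4$airflow <- mk("airflow", 90)
  expect_equal(ncol(assemble(traces4, spec_d, meta)$x), 90)
  traces5 <- traces3; traces5$airflow <- mk("airflow", 400)
  expect_equal(assemble(traces5, spec_d, meta)$exclude_reason,
               "channel_length_mismatch")
})

test_that("inclusion rules follow age, split-night and the 3-hour bound", {
  meta_ok <- subject_meta("ok", age = 40)
  rec <- psg_record(meta_ok, list(test_trace(n = 128)))
  h_ok <- hypnogram(rep(c("W", "N2"), c(40, 360)))     # exactly 3 h sleep
  expect_true(inclusion_filter(rec, h_ok)$keep)
  expect_equal(inclusion_filter(rec, h_ok)$tst_h, 3)
  h_short <- hypnogram(rep(c("W", "N2"), c(52, 348)))  # 2.9 h
  r <- inclusion_filter(rec, h_short)
  expect_false(r$keep)
  expect_equal(r$reason, "tst_lt_3h")
  rec_na <- psg_record(subject_meta("na"), list(test_trace(n = 128)))
  expect_equal(inclusion_filter(rec_na, h_ok)$reason, "age_unknown")
  expect_equal(inclusion_filter(rec, h_ok, split_night = TRUE)$reason,
               "cpap_split_night")
  expect_warning(inclusion_filter(rec, NULL), "hypnogram")
})

test_that("ages above 89 are stored as 90 with the truncation flag", {
  m <- subject_meta("old", age = 93)
  expect_equal(m$age, 90)
  expect_true(m$age_truncated)
  expect_false(subject_meta("mid", age = 89)$age_truncated)
})

test_that("full preprocessing emits a bounded, finite 128 Hz stack", {
  spec <- sim_spec(n_subjects = 1, rec_hours = 0.25, seed = 21)
  s <- gen_subject(spec, 55, 0, 22, "pp")
  pre <- preprocess_record(s$record, channel_set_spec("a"),
                           montage = c("C3-M2", "C4-M1"))
  expect_false(pre$excluded)
  expect_equal(pre$fs, 128)
  expect_true(all(is.finite(pre$x)))
  # the bulk of a normalized channel sits within [-2, 2]
  expect_gt(mean(abs(pre$x[1, ]) <= 2), 0.95)
  # store round trip composed with assemble is the identity on (x, mask)
  path <- withr::local_tempfile()
  write_tensor_store(pre, path)
  back <- read_tensor_store(path, expect_channels = pre$channels)
  expect_lt(max(abs(back$x - pre$x)), 1e-5)
  expect_equal(back$mask, pre$mask)
})
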