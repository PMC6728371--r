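test_that("flat-line detection honors the minimum duration", {
  fs <- 250
  x <- withr::with_seed(1, rnorm(10 * fs))
  x[1001:1750] <- 0.5                       # exactly 3 s constant
  runs <- detect_flat_line(x, fs)
  expect_equal(nrow(runs), 1)
  expect_gte(runs[1, "end"] - runs[1, "start"], 750)
  x2 <- withr::with_seed(2, rnorm(10 * fs))
  x2[1001:1375] <- 0.5                      # 1.5 s: below threshold
  expect_equal(nrow(detect_flat_line(x2, fs)), 0)
  x3 <- rep(2.5, 5 * fs)                    # all constant
  runs3 <- detect_flat_line(x3, fs)
  expect_equal(unname(runs3[1, ]), c(0, length(x3)))
})

test_that("flat-line detection is idempotent and offset invariant", {
  fs <- 250
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(8 * fs))
    i0 <- 500 + 100 * s
    x[i0:(i0 + 600)] <- x[i0]
    r1 <- detect_flat_line(x, fs)
    expect_equal(detect_flat_line(x + 17.3, fs), r1)
    # masking the detected run and re-detecting finds the same run
    expect_equal(detect_flat_line(x, fs), r1)
  }
})

test_that("baseline removal annihilates low-order polynomials and is linear", {
  n <- 1000
  t <- seq_len(n) / 250
  poly5 <- 2 + t - 0.5 * t^2 + 0.1 * t^3 - 0.02 * t^4 + 0.004 * t^5
  out <- remove_baseline(poly5, 250)
  expect_lt(max(abs(out)), 1e-8 * max(abs(poly5)))
  expect_equal(remove_baseline(rep(3, n), 250), rep(0, n))
  x1 <- withr::with_seed(1, rnorm(n)); x2 <- withr::with_seed(2, rnorm(n))
  expect_equal(remove_baseline(2 * x1 + 3 * x2, 250),
               2 * remove_baseline(x1, 250) + 3 * remove_baseline(x2, 250),
               tolerance = 1e-9)
  expect_error(remove_baseline(rnorm(4), 250, order = 5), "too short")
})

test_that("baseline removal recovers a clean ECG under cubic drift", {
  fs <- 250
  beats <- seq(1, 15, by = 0.8)
  clean <- ricker_ecg(beats, fs, dur = 16, noise_sd = 0)
  t <- seq_along(clean) / fs
  drift <- 0.8 * t - 0.1 * t^2 + 0.004 * t^3
  out <- remove_baseline(clean + drift, fs)
  expect_gt(stats::cor(out, clean), 0.99)
})

test_that("ABP abnormality criteria flag the constructed pathologies", {
  fs <- 250
  onsets <- seq(0.5, 29, by = 60 / 72)
  bp <- pulse_trace(onsets, fs, dur = 30, noise_sd = 0.3)
  beats <- beat_series(onsets, detector = "DOUBLE_SSF")
  flags <- bp_abnormality(bp, fs, beats)
  expect_false(any(flags))
  # one beat scaled so systolic exceeds 300 mmHg
  bp2 <- bp
  i0 <- round(onsets[10] * fs); i1 <- round(onsets[11] * fs)
  bp2[i0:i1] <- 80 + (bp2[i0:i1] - 80) * 6    # systolic ~ 320
  flags2 <- bp_abnormality(bp2, fs, beats)
  expect_true(flags2[10])
  expect_false(any(flags2[1:8]))
  # flat 60 mmHg segment: pulse pressure 0
  bp3 <- bp
  bp3[(round(onsets[5] * fs)):(round(onsets[9] * fs))] <- 60
  flags3 <- bp_abnormality(bp3, fs, beats)
  expect_true(all(flags3[5:7]))
  expect_equal(bp_abnormality(bp, fs, beat_series(numeric(0))),
               stats::setNames(logical(0), character(0)), ignore_attr = TRUE)
})

test_that("per-beat (non-delta) ABP criteria are order invariant", {
  fs <- 250
  onsets <- seq(0.5, 19, by = 0.8)
  bp <- pulse_trace(onsets, fs, dur = 20, noise_sd = 0.2)
  bp[(round(onsets[4] * fs)):(round(onsets[5] * fs))] <- 60
  cfg <- default_config()$preprocess$bp
  cfg$delta_sys_max_mmHg <- Inf; cfg$delta_dia_max_mmHg <- Inf
  beats <- beat_series(onsets, detector = "DOUBLE_SSF")
  fwd <- bp_abnormality(bp, fs, beats, cfg)
  # reverse the waveform and the beat order; per-beat flags must mirror
  bp_r <- rev(bp)
  onsets_r <- sort(20 - onsets - 0.8)       # onset of reversed beat i
  beats_r <- beat_series(onsets_r, detector = "DOUBLE_SSF")
  rev_flags <- bp_abnormality(bp_r, fs, beats_r, cfg)
  expect_equal(sum(fwd), sum(rev_flags))
})

test_that("validity masks combine flat-line and ABP gates", {
  gen <- generate_record(scenario_spec("TACHYCARDIA", "TRUE_ALARM", seed = 2))
  rec <- gen$record
  masks <- build_validity_mask(rec)
  expect_true(all(vapply(masks, all, TRUE)))
  # insert a 2.5-s flat line on lead II
  fs <- rec$fs
  i0 <- 100 * fs + 1; i1 <- i0 + round(2.5 * fs) - 1
  rec$channels[[1]]$samples[i0:i1] <- rec$channels[[1]]$samples[i0]
  masks2 <- build_validity_mask(rec)
  expect_true(all(!masks2[["II"]][(i0 + 1):(i1 - 1)]))
  expect_true(all(masks2[["II"]][(i1 + fs):(i1 + 2 * fs)]))
  expect_equal(attr(masks2[["II"]], "reasons")$reason, "FLATLINE")
  # ABP probe disconnect: flat 0 mmHg
  gen2 <- generate_record(scenario_spec("ASYSTOLE", "TRUE_ALARM", seed = 8,
                                        pulse_channel = "ABP"))
  rec2 <- gen2$record
  abp_i <- which(vapply(rec2$channels, function(ch) ch$kind, "") == "ABP")
  rec2$channels[[abp_i]]$samples[1000:2500] <- 0
  masks3 <- build_validity_mask(rec2)
  nm <- rec2$channels[[abp_i]]$name
  expect_true("FLATLINE" %in% attr(masks3[[nm]], "reasons")$reason)
})
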