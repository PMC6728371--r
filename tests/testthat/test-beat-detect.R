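test_that("slope sum function matches its closed forms", {
  fs <- 250
  w <- round(0.128 * fs)   # 32 samples
  ramp <- 0.3 * seq_len(500)
  y <- ssf(ramp, fs)
  expect_equal(unname(y[(w + 2):500]), rep(0.3 * w, 500 - w - 1),
               tolerance = 1e-12)
  expect_equal(ssf(rev(ramp), fs), rep(0, 500))
  step <- c(rep(0, 100), rep(1, 200))
  ys <- ssf(step, fs)
  expect_equal(sum(ys == 1), w)
  expect_true(all(ys %in% c(0, 1)))
})

test_that("double SSF is non-negative for arbitrary signals", {
  fs <- 250
  for (s in 1:10) {
    x <- withr::with_seed(s, cumsum(rnorm(2000)))
    expect_true(all(ssf(ssf(x, fs), fs) >= 0))
  }
})

test_that("wavelet QRS detection recovers clean beats to within 40 ms", {
  fs <- 250
  beats <- seq(0.5, 59.5, by = 1.0)          # 60 bpm
  x <- ricker_ecg(beats, fs, dur = 60, noise_sd = 0.02)
  b <- detect_qrs(x, fs)
  expect_true(abs(length(b$times) - 60) <= 1)
  err <- vapply(beats, function(t) min(abs(b$times - t)), 0)
  expect_lt(max(err), 0.040)
})

test_that("QRS detection is invariant to scaling and offset", {
  fs <- 250
  x <- ricker_ecg(seq(0.5, 29.5, by = 0.8), fs, dur = 30, noise_sd = 0.02)
  b1 <- detect_qrs(x, fs)
  b2 <- detect_qrs(10 * x + 3, fs)
  expect_equal(b2$times, b1$times)
})

test_that("no detections appear inside a beat-free gap", {
  fs <- 250
  beats <- seq(0.5, 59.5, by = 1.0)
  beats <- beats[beats <= 30 | beats >= 34.5]
  x <- ricker_ecg(beats, fs, dur = 60, noise_sd = 0.02)
  b <- detect_qrs(x, fs)
  expect_equal(sum(b$times > 30.3 & b$times < 34.2), 0)
})

test_that("QRS detection rejects unsupported rates and degenerate input", {
  expect_error(detect_qrs(rnorm(100), fs = 50), "unsupported")
  expect_length(detect_qrs(rep(0.2, 5000), 250)$times, 0)
  expect_length(detect_qrs(rnorm(5000), 250,
                           mask = rep(FALSE, 5000))$times, 0)
})

test_that("pulse onsets are recovered within 60 ms, wander or not", {
  fs <- 250
  onsets <- seq(0.5, 58.5, by = 60 / 72)     # 72 bpm
  x <- pulse_trace(onsets, fs, dur = 60, noise_sd = 0.5)
  b <- detect_pulse_onsets(x, fs)
  expect_true(abs(length(b$times) - length(onsets)) <= 2)
  err <- vapply(onsets, function(t) min(abs(b$times - t)), 0)
  expect_lt(max(err), 0.060)
  # slow sinusoidal wander with amplitude equal to the pulse pressure
  t <- (seq_along(x) - 1) / fs
  bw <- detect_pulse_onsets(x + 40 * sin(2 * pi * 0.2 * t), fs)
  errw <- vapply(onsets, function(t) min(abs(bw$times - t)), 0)
  expect_lt(max(errw), 0.060)
  expect_equal(length(bw$times), length(b$times))
  expect_length(detect_pulse_onsets(rep(80, 5000), fs)$times, 0)
})

test_that("band envelopes separate frequency content and stay non-negative", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  env <- estimate_envelopes(sin(2 * pi * 10 * t), fs)
  mid <- (2 * fs):(8 * fs)
  expect_gt(mean(env$envelopes$qrs[mid]), 0.4)
  expect_lt(mean(env$envelopes$high[mid]), 0.02)
  expect_true(all(vapply(env$envelopes, function(e) all(e >= 0), TRUE)))
  z <- estimate_envelopes(rep(0, 1000), fs)
  expect_true(all(vapply(z$envelopes, function(e) all(e == 0), TRUE)))
  expect_error(estimate_envelopes(rnorm(100), fs,
                                  bands = list(bad = c(50, 200))), "band")
  # impulse train: envelopes peak at the impulses
  x <- rep(0, 5 * fs); idx <- seq(250, 1000, by = 250); x[idx] <- 1
  ei <- estimate_envelopes(x, fs)
  peaks <- order(ei$envelopes$high, decreasing = TRUE)[seq_along(idx)]
  expect_true(all(vapply(peaks, function(p) min(abs(p - idx)) < 25, TRUE)))
})

test_that("pacing spikes are rejected while true beats are kept", {
  gen <- generate_record(scenario_spec("TACHYCARDIA", "FALSE_ALARM",
                                       seed = 5))   # pacing variant
  cfg <- default_config()
  pr <- process_record(gen$record, cfg)
  b <- pr$beats[["II"]]
  truth <- gen$truth$beat_times
  is_spike <- vapply(b$times, function(t) min(abs(truth - t)) > 0.06, TRUE)
  expect_gt(mean(b$rejected[is_spike] == "PACING_SPIKE"), 0.8)
  expect_gt(mean(b$rejected[!is_spike] == "NONE"), 0.8)
})

test_that("clean records incur no rejections; empty series pass through", {
  fs <- 250
  x <- ricker_ecg(seq(0.5, 29.5, by = 0.8), fs, dur = 30, noise_sd = 0.02)
  b <- detect_qrs(x, fs)
  env <- estimate_envelopes(x, fs)
  expect_true(all(reject_false_peaks(b, env)$rejected == "NONE"))
  e0 <- beat_series(numeric(0))
  expect_length(reject_false_peaks(e0, env)$times, 0)
  expect_length(flag_ventricular(e0, env, fs)$times, 0)
})

test_that("wide smooth complexes are flagged ventricular, narrow ones not", {
  gen <- generate_record(scenario_spec("VTACH", "TRUE_ALARM", seed = 4))
  pr <- process_record(gen$record, default_config())
  b <- icualarms:::window_beats(pr$beats[["II"]], c(285, 300))
  vt_times <- gen$truth$beat_times[gen$truth$ventricular]
  is_vt <- vapply(b$times, function(t) any(abs(vt_times - t) < 0.06), TRUE)
  expect_gte(mean(b$ventricular[is_vt]), 0.9)
  expect_lt(mean(b$ventricular[!is_vt]), 0.1)
})

test_that("QRS sensitivity and positive predictivity hold across seeds", {
  fs <- 250
  sens <- ppv <- numeric(0)
  for (s in 1:8) {
    rate <- 55 + 5 * (s %% 4)
    beats <- seq(0.5, 58, by = 60 / rate)
    x <- ricker_ecg(beats, fs, dur = 60, noise_sd = 0.05, seed = s)  # ~13 dB
    b <- detect_qrs(x, fs)
    hits <- vapply(beats, function(t) min(abs(b$times - t)) < 0.05, TRUE)
    claims <- vapply(b$times, function(t) min(abs(beats - t)) < 0.05, TRUE)
    sens <- c(sens, mean(hits)); ppv <- c(ppv, mean(claims))
  }
  expect_true(all(sens >= 0.98))
  expect_true(all(ppv >= 0.98))
})
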