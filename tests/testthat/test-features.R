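fs <- 250

test_that("template correlation is 1 for identical beats, ~0 for noise", {
  beats <- seq(1, 19, by = 1)
  x <- ricker_ecg(beats, fs, dur = 20, noise_sd = 0)
  bs <- beat_series(beats)
  expect_equal(sqi_correlation(x, fs, bs), 1.0, tolerance = 1e-9)
  vals <- vapply(1:10, function(s) {
    xn <- withr::with_seed(s, rnorm(20 * fs))
    sqi_correlation(xn, fs, bs)
  }, 0)
  expect_lt(max(abs(vals)), 0.3)
  expect_true(is.na(sqi_correlation(x, fs, beat_series(c(1, 2)))))
})

test_that("peak-height stability counts beats near the median amplitude", {
  b_eq <- beat_series(1:10, amplitudes = rep(2, 10))
  expect_equal(sqi_peak_height_stability(b_eq), 1.0)
  # a majority of beats at unit amplitude anchors the median there, so the
  # 10x outlier beats all fall outside the 30% band
  b_out <- beat_series(1:11, amplitudes = c(rep(1, 6), rep(10, 5)))
  expect_equal(sqi_peak_height_stability(b_out), 6 / 11)
  # an even 1x/10x split puts the interpolated median between the clusters:
  # nothing is within 30% of it
  b_half <- beat_series(1:10, amplitudes = rep(c(1, 10), 5))
  expect_equal(sqi_peak_height_stability(b_half), 0)
  expect_true(is.na(sqi_peak_height_stability(beat_series(1:2,
                                                          amplitudes = c(1, 1)))))
  # uniform amplitudes on [0.5 m, 1.5 m]: P(within 30% of the median) ~ 0.6
  vals <- vapply(1:40, function(s) {
    a <- withr::with_seed(s, runif(200, 0.5, 1.5))
    sqi_peak_height_stability(beat_series(seq_along(a), amplitudes = a))
  }, 0)
  expect_equal(mean(vals), 0.6, tolerance = 0.03)
})

test_that("sharpness ranks impulse trains above smooth oscillations", {
  n <- 10 * fs
  x <- rep(0, n); idx <- seq(fs, 9 * fs, by = fs); x[idx] <- 1
  bs <- beat_series((idx - 1) / fs, amplitudes = rep(1, length(idx)))
  expect_gte(sqi_sharpness(x, fs, bs), 10)
  t <- (seq_len(n) - 1) / fs
  sine <- sin(2 * pi * 2 * t)
  crests <- (which(diff(sign(diff(sine))) == -2) + 1)
  crests <- crests[sine[crests] > 0.99]
  bsin <- beat_series((crests - 1) / fs)
  m <- round(0.06 * fs)
  i <- crests[3]
  expected <- 1 / mean(abs(sine[c((i - m):(i - 2), (i + 2):(i + m))]))
  got <- sqi_sharpness(sine, fs, bsin)
  expect_equal(got, expected, tolerance = 0.01)
  expect_gt(sqi_sharpness(x, fs, bs), got)
})

test_that("periodicity is high for periodic signals, low for noise and ramps", {
  t <- (0:(10 * fs - 1)) / fs
  per <- sin(2 * pi * t / 0.8) + 0.3 * sin(4 * pi * t / 0.8)
  expect_gte(sqi_periodicity(per, fs), 0.99)
  noise_vals <- vapply(1:10, function(s)
    sqi_periodicity(withr::with_seed(s, rnorm(10 * fs)), fs), 0)
  expect_lt(max(noise_vals), 0.3)
  # ramp: freeze the expectation from an independent direct computation of
  # the unbiased normalized autocorrelation at the best lag
  ramp <- seq_len(10 * fs) * 0.001
  r0 <- ramp - mean(ramp)
  lags <- round(0.24 * fs):round(2.4 * fs)
  direct <- max(vapply(lags, function(l) {
    n <- length(r0)
    sum(r0[1:(n - l)] * r0[(l + 1):n]) / ((n - l) * mean(r0^2))
  }, 0))
  ramp_val <- sqi_periodicity(ramp, fs)
  expect_equal(ramp_val, min(direct, 1), tolerance = 1e-9)
  expect_lt(ramp_val, sqi_periodicity(per, fs))
  expect_true(is.na(sqi_periodicity(rnorm(2 * fs), fs)))
})

test_that("swing features match closed forms", {
  expect_true(all(is.na(unlist(swing_features(rnorm(100), fs))) |
                    unlist(swing_features(rep(1, 5 * fs), fs)) == 0))
  sw0 <- swing_features(rep(2, 10 * fs), fs)
  expect_equal(unlist(sw0), c(swing_min = 0, swing_max = 0, swing_mean = 0))
  t <- (0:(10 * fs - 1)) / fs
  sw <- swing_features(sin(2 * pi * 5 * t), fs)
  expect_equal(unlist(sw), c(swing_min = 2, swing_max = 2, swing_mean = 2),
               tolerance = 0.01)   # sampling grid clips the crests slightly
  x <- rep(c(5, -5), 5 * fs)
  x[(4 * fs + 1):(5 * fs)] <- 0.1           # one quiet sub-window
  expect_lt(swing_features(x, fs)$swing_min, 1)
  expect_equal(swing_features(x, fs)$swing_max, 10)
})

test_that("blank-area swing separates silent gaps from artifact-filled ones", {
  x <- ricker_ecg(c(1, 2, 3, 8.5, 9.5), fs, dur = 10, noise_sd = 0.005)
  bs <- beat_series(c(1, 2, 3, 8.5, 9.5))
  silent <- blank_area_swing(x, fs, bs)
  expect_lt(silent, 0.1)
  xa <- x
  xa[(4.5 * fs):(7 * fs)] <- xa[(4.5 * fs):(7 * fs)] +
    withr::with_seed(1, rnorm(2.5 * fs + 1, sd = 0.5))
  expect_gt(blank_area_swing(xa, fs, bs), 10 * silent)
  expect_equal(blank_area_swing(rep(1, 5 * fs), fs, beat_series(numeric(0))), 0)
})

test_that("spectral features match single- and two-tone constructions", {
  t <- (0:(16 * fs - 1)) / fs
  sp <- spectral_features(sin(2 * pi * 5 * t), fs)
  expect_equal(sp$mean_freq, 5, tolerance = 0.1)
  expect_equal(sp$median_freq, 5, tolerance = 0.1)
  expect_gte(sp$max_power_ratio, 0.9)
  two <- spectral_features(sin(2 * pi * 3 * t) + sin(2 * pi * 9 * t), fs)
  expect_equal(two$mean_freq, 6, tolerance = 0.15)
  noise_ratios <- vapply(1:8, function(s)
    spectral_features(withr::with_seed(s, rnorm(10 * fs)), fs)$max_power_ratio,
    0)
  expect_lt(max(noise_ratios), 0.15)   # frozen from the Monte-Carlo draws
  expect_lt(mean(noise_ratios), 0.1)
  expect_true(is.na(spectral_features(rnorm(fs), fs)$mean_freq))
})

test_that("spectral mean frequency is exact to one bin for any window >= 4 s", {
  for (dur in c(4, 7, 10, 16)) {
    t <- (0:(dur * fs - 1)) / fs
    sp <- spectral_features(sin(2 * pi * 6.3 * t), fs)
    expect_lt(abs(sp$mean_freq - 6.3), 1 / dur + 1e-9)
  }
})

test_that("rr/hr run features match closed forms and edge conventions", {
  b <- beat_series(seq(2, 28, by = 2))
  r <- rr_hr_features(b, c(1, 29))
  expect_equal(r$min_hr_5beat_bpm, 30)
  expect_equal(r$max_rr_s, 2)
  b2 <- beat_series(seq(1, by = 0.4, length.out = 20))
  r2 <- rr_hr_features(b2, c(0.5, 9))
  expect_equal(r2$max_hr_17beat_bpm, 150, tolerance = 1e-9)
  r3 <- rr_hr_features(beat_series(numeric(0)), c(284, 300))
  expect_equal(r3$max_rr_s, 16)
  expect_true(is.na(r3$min_hr_5beat_bpm))
  expect_equal(r3$vt_run_max_len, 0)
})

test_that("run statistics agree with brute-force enumeration", {
  for (s in 1:50) {
    t <- withr::with_seed(s, sort(runif(sample(0:60, 1), 0, 30)))
    t <- t[c(TRUE, diff(t) > 0.25)]
    vent <- withr::with_seed(s + 1, runif(length(t)) < 0.3)
    b <- beat_series(t, ventricular = vent)
    r <- rr_hr_features(b, c(0, 30))
    expect_equal(r$max_rr_s, max(diff(c(0, t, 30))))
    for (spec_k in list(c(5, "min_hr_5beat_bpm"), c(4, "slowest_4beat_bpm"))) {
      k <- as.integer(spec_k[1])
      rates <- brute_run_rates(t, k)
      if (length(rates)) expect_equal(r[[spec_k[2]]], min(rates))
      else expect_true(is.na(r[[spec_k[2]]]))
    }
    rates17 <- brute_run_rates(t, 17)
    if (length(rates17)) expect_equal(r$max_hr_17beat_bpm, max(rates17))
    else expect_true(is.na(r$max_hr_17beat_bpm))
  }
})

test_that("feature vectors follow the registry and the VF augmentation", {
  cfg <- default_config()
  gen <- generate_record(scenario_spec("ASYSTOLE", "TRUE_ALARM", seed = 3))
  pr <- process_record(gen$record, cfg)
  ft <- extract_features(gen$record, pr$beats, pr$masks, pr$env, cfg)
  expect_equal(nrow(ft), 1)
  nms <- feature_names(ft)
  expect_true(all(c("ecg1_max_rr", "ecg2_max_rr", "ppg_max_rr",
                    "ecg1_swing_max", "ecg1_sqi_correlation",
                    "ecg1_blank_area_swing") %in% nms))
  expect_false(any(grepl("mean_freq|max_power", nms)))
  expect_true(all(is.na(unlist(ft[paste0("abp_", c("max_rr", "swing_min"))]))))
  # true VF alarm in training mode: four windows
  genv <- generate_record(scenario_spec("VFIB", "TRUE_ALARM", seed = 5))
  prv <- process_record(genv$record, cfg)
  ftv <- extract_features(genv$record, prv$beats, prv$masks, prv$env, cfg,
                          training = TRUE)
  expect_equal(nrow(ftv), 4)
  expect_equal(ftv$window_start, c(293, 294, 295, 296))
  ftv2 <- extract_features(genv$record, prv$beats, prv$masks, prv$env, cfg,
                           training = FALSE)
  expect_equal(nrow(ftv2), 1)
})

test_that("signal-quality indices are invariant to positive scaling", {
  cfg <- default_config()
  gen <- generate_record(scenario_spec("VTACH", "TRUE_ALARM", seed = 9))
  rec <- gen$record
  pr <- process_record(rec, cfg)
  ft1 <- extract_features(rec, pr$beats, pr$masks, pr$env, cfg)
  rec2 <- rec
  for (i in seq_along(rec2$channels))
    rec2$channels[[i]]$samples <- rec2$channels[[i]]$samples * 5
  pr2 <- process_record(rec2, cfg)
  ft2 <- extract_features(rec2, pr2$beats, pr2$masks, pr2$env, cfg)
  for (nm in grep("sqi_", feature_names(ft1), value = TRUE)) {
    if (is.na(ft1[[nm]])) next
    expect_equal(ft2[[nm]], ft1[[nm]], tolerance = 1e-6, label = nm)
  }
})
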