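# Shared fixture builders.  Everything is generated in code at test time;
# heavyweight artifacts (the scenario benchmark and its feature tables) are
# cached for the session so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# clean ECG trace: Ricker QRS complexes with T/P bumps at given beat times
ricker_ecg <- function(beat_times, fs = 250, dur = 60, noise_sd = 0.02,
                       t_amp = 0.18, qrs_sigma = 0.02, amp = 1, seed = 1) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  ricker <- function(tt, s) (1 - (tt / s)^2) * exp(-tt^2 / (2 * s^2))
  for (bt in beat_times) {
    idx <- which(abs(t - bt) < 0.12)
    x[idx] <- x[idx] + amp * ricker(t[idx] - bt, qrs_sigma)
    idxT <- which(abs(t - bt - 0.25) < 0.18)
    x[idxT] <- x[idxT] + t_amp * exp(-(t[idxT] - bt - 0.25)^2 / (2 * 0.05^2))
  }
  if (noise_sd > 0) x <- x + withr::with_seed(seed, rnorm(n, sd = noise_sd))
  x
}

# asymmetric arterial-pulse trace (raised-cosine upstroke, exponential decay)
pulse_trace <- function(onsets, fs = 250, dur = 60, sys = 120, dia = 80,
                        noise_sd = 0.5, seed = 1) {
  n <- round(dur * fs)
  x <- rep(dia, n)
  k <- length(onsets)
  med <- if (k > 1) stats::median(diff(onsets)) else 0.8
  for (i in seq_len(k)) {
    t0 <- onsets[i]
    t1 <- if (i < k) onsets[i + 1] else t0 + med
    i0 <- round(t0 * fs) + 1L; i1 <- min(n, round(t1 * fs))
    if (i0 >= i1 || i0 < 1) next
    seg_t <- ((i0:i1) - 1) / fs - t0
    shape <- ifelse(seg_t < 0.12, 0.5 - 0.5 * cos(pi * pmin(seg_t / 0.12, 1)),
                    exp(-(seg_t - 0.12) / 0.35))
    x[i0:i1] <- dia + (sys - dia) * shape
  }
  if (noise_sd > 0) x <- x + withr::with_seed(seed, rnorm(n, sd = noise_sd))
  x
}

# labeled feature table with `informative` shifted features and noise features
make_table <- function(n = 60, p = 8, informative = 2, sep = 3, seed = 42,
                       arrhythmia = "ASYSTOLE",
                       names_ = paste0("f", seq_len(p))) {
  withr::with_seed(seed, {
    y <- rep(c("TRUE_ALARM", "FALSE_ALARM"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(informative))
      X[y == "TRUE_ALARM", j] <- X[y == "TRUE_ALARM", j] + sep
    df <- as.data.frame(X)
    names(df) <- names_
    df <- cbind(data.frame(record_id = paste0("r", seq_len(n)),
                           window_start = 284, label = y,
                           stringsAsFactors = FALSE), df)
    new_feature_table(df, arrhythmia)
  })
}

# scenario benchmark feature tables, cached (shared by the feature-separation
# and end-to-end checks); returns list(tables, n_per_cell)
benchmark_tables <- function(n_per_cell, master_seed = 2024) {
  cached(sprintf("tables_%d_%d", n_per_cell, master_seed), {
    cfg <- default_config()
    tabs <- list()
    counter <- 0
    for (type in c("ASYSTOLE", "BRADYCARDIA", "TACHYCARDIA", "VFIB", "VTACH"))
      for (lab in c("TRUE_ALARM", "FALSE_ALARM"))
        for (i in seq_len(n_per_cell)) {
          counter <- counter + 1
          seed <- icualarms:::derive_seed(master_seed, counter * 101)
          gen <- generate_record(scenario_spec(type, lab, seed,
                                               pulse_channel = if (counter %% 2)
                                                 "PLETH" else "ABP"))
          rec <- gen$record
          rec$record_id <- sprintf("%s%04d", tolower(substr(type, 1, 1)), counter)
          if (type == "VFIB") rec$record_id <- sprintf("f%04d", counter)
          pr <- process_record(rec, cfg)
          ft <- extract_features(rec, pr$beats, pr$masks, pr$env, cfg,
                                 training = TRUE)
          tabs[[type]] <- if (is.null(tabs[[type]])) ft
                          else bind_feature_tables(tabs[[type]], ft)
        }
    tabs
  })
}

# rank-sum AUC of feature values, true alarms vs false alarms
rank_auc <- function(true_vals, false_vals) {
  tv <- true_vals[is.finite(true_vals)]
  fv <- false_vals[is.finite(false_vals)]
  r <- rank(c(tv, fv))
  nt <- length(tv); nf <- length(fv)
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nf)
}

# brute-force run-statistics oracle used against rr_hr_features and
# annotate_truth (plain loops, no shared code with the implementation)
brute_run_rates <- function(t, k) {
  if (length(t) < k) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(length(t) - k + 1))
    out <- c(out, 60 * (k - 1) / (t[i + k - 1] - t[i]))
  out
}

brute_verdicts <- function(t, vent, dur) {
  gaps <- diff(c(0, t, dur))
  asys <- FALSE
  for (g in gaps) if (g >= 4 - 1e-9) asys <- TRUE
  brady <- any(brute_run_rates(t, 5) < 40 - 1e-9)
  tachy <- any(brute_run_rates(t, 17) > 140 + 1e-9)
  vt <- FALSE
  i <- 1
  while (i <= length(t)) {
    if (vent[i]) {
      j <- i
      while (j < length(t) && vent[j + 1]) j <- j + 1
      if (j - i + 1 >= 5 &&
          60 * (j - i) / (t[j] - t[i]) > 100 + 1e-9) vt <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  c(ASYSTOLE = asys, BRADYCARDIA = brady, TACHYCARDIA = tachy, VTACH = vt)
}
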