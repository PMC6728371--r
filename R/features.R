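#' Template-correlation signal quality index
#'
#' Extracts a fixed window (default +/- 250 ms) around each accepted
#' fiducial, averages the windows into a template, and returns the mean
#' Pearson correlation of the individual beats with the template.  High for
#' stable morphology (clean sinus rhythm, monomorphic VT), low for artifact.
#'
#' @param x Signal vector (one analysis window).
#' @param fs Sampling rate, Hz.
#' @param beats A [beat_series()] with times relative to `x`'s start.
#' @param half_window_s Half window around the fiducial, seconds.
#' @return Correlation in `[-1, 1]`; `NA` with fewer than 3 usable beats.
#' @export
sqi_correlation <- function(x, fs, beats,
                            half_window_s = default_config()$features$template_half_window_s) {
  t <- accepted_beats(beats)$times
  m <- round(half_window_s * fs)
  idx <- round(t * fs) + 1L
  ok <- idx - m >= 1 & idx + m <= length(x)
  idx <- idx[ok]
  if (length(idx) < 3) return(NA_real_)
  win <- vapply(idx, function(i) x[(i - m):(i + m)], numeric(2 * m + 1))
  template <- rowMeans(win)
  if (stats::sd(template) == 0) return(NA_real_)
  cors <- apply(win, 2, function(b)
    if (stats::sd(b) == 0) NA_real_ else stats::cor(b, template))
  cors <- cors[is.finite(cors)]
  if (!length(cors)) return(NA_real_)
  mean(cors)
}

#' Peak-height stability signal quality index
#'
#' Fraction of accepted beats whose absolute fiducial amplitude lies within
#' +/- 30% of the median absolute amplitude.
#'
#' @param beats A [beat_series()].
#' @param band Relative half-band (0.3 = within 30%).
#' @return Value in `[0, 1]`; `NA` with fewer than 3 accepted beats.
#' @export
sqi_peak_height_stability <- function(beats,
                                      band = default_config()$features$stability_band) {
  a <- abs(accepted_beats(beats)$amplitudes)
  a <- a[is.finite(a)]
  if (length(a) < 3) return(NA_real_)
  med <- stats::median(a)
  mean(a >= (1 - band) * med & a <= (1 + band) * med)
}

#' Sharpness signal quality index
#'
#' Median over accepted beats of the absolute fiducial amplitude divided by
#' the mean absolute signal in +/- 60 ms around the fiducial (the fiducial
#' +/- 1 sample excluded).  QRS complexes are much sharper than their
#' surroundings; smooth oscillations score near 1.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param beats A [beat_series()].
#' @param half_window_s Half neighborhood, seconds.
#' @return Non-negative sharpness; `NA` with fewer than 3 usable beats or a
#'   zero denominator everywhere.
#' @export
sqi_sharpness <- function(x, fs, beats,
                          half_window_s = default_config()$features$sharpness_half_window_s) {
  t <- accepted_beats(beats)$times
  m <- max(2L, round(half_window_s * fs))
  idx <- round(t * fs) + 1L
  ok <- idx - m >= 1 & idx + m <= length(x)
  idx <- idx[ok]
  if (length(idx) < 3) return(NA_real_)
  vals <- vapply(idx, function(i) {
    nb <- c((i - m):(i - 2), (i + 2):(i + m))
    den <- mean(abs(x[nb]))
    num <- abs(x[i])
    # an exactly silent neighborhood around a non-zero fiducial is maximally
    # sharp: floor the denominator at 1% of the peak (sharpness capped at 100)
    if (den == 0) den <- 0.01 * num
    if (den == 0) NA_real_ else num / den
  }, 0)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  stats::median(vals)
}

#' Periodicity signal quality index
#'
#' Maximum of the unbiased, mean-removed normalized autocorrelation over
#' lags spanning 25-250 bpm (0.24-2.4 s), clipped to `[0, 1]`.  Near 1 for
#' any strongly periodic rhythm, low for noise.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param mask Optional validity mask; the longest unmasked run is used.
#' @param lag_range_s Lag range searched, seconds.
#' @param min_duration_s Minimum usable signal, seconds.
#' @return Value in `[0, 1]`, or `NA` on insufficient unmasked data.
#' @export
sqi_periodicity <- function(x, fs, mask = NULL,
                            lag_range_s = default_config()$features$periodicity_lag_s,
                            min_duration_s = 5) {
  x <- .longest_unmasked(x, mask)
  n <- length(x)
  if (n < min_duration_s * fs) return(NA_real_)
  x0 <- x - mean(x)
  v <- mean(x0^2)
  if (v == 0) return(NA_real_)
  lags <- seq(max(1L, round(lag_range_s[1] * fs)),
              min(n - 2L, round(lag_range_s[2] * fs)))
  if (!length(lags)) return(NA_real_)
  r <- vapply(lags, function(l)
    sum(x0[1:(n - l)] * x0[(l + 1):n]) / ((n - l) * v), 0)
  min(max(max(r), 0), 1)
}

.longest_unmasked <- function(x, mask) {
  if (is.null(mask) || all(mask)) return(x)
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (!length(ok)) return(numeric(0))
  j <- ok[which.max(r$lengths[ok])]
  x[starts[j]:ends[j]]
}

#' Swing features over fixed sub-windows
#'
#' Swing of a sub-window is its max minus min.  The signal is cut into
#' non-overlapping sub-windows (default 1 s); sub-windows touching masked
#' samples are skipped.  Large swings indicate high-amplitude activity or
#' artifact; near-zero swing indicates a blank (e.g. asystolic) trace.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param sub_window_s Sub-window length, seconds.
#' @param mask Optional validity mask.
#' @return Named list `swing_min`, `swing_max`, `swing_mean` (all `NA` when
#'   no clean sub-window exists).
#' @export
swing_features <- function(x, fs,
                           sub_window_s = default_config()$features$swing_sub_window_s,
                           mask = NULL) {
  w <- max(2L, round(sub_window_s * fs))
  k <- floor(length(x) / w)
  miss <- list(swing_min = NA_real_, swing_max = NA_real_, swing_mean = NA_real_)
  if (k < 2) return(miss)
  sw <- numeric(0)
  for (i in seq_len(k)) {
    ix <- ((i - 1) * w + 1):(i * w)
    if (!is.null(mask) && !all(mask[ix])) next
    sw <- c(sw, max(x[ix]) - min(x[ix]))
  }
  if (!length(sw)) return(miss)
  list(swing_min = min(sw), swing_max = max(sw), swing_mean = mean(sw))
}

#' Swing inside the longest beat-free span
#'
#' The "blank area" of an asystole window is the longest inter-beat interval
#' (window edges count as interval edges); its swing separates a genuinely
#' silent trace (true asystole) from artifact that merely hid the beats.
#' With no beats the whole window is the blank area.
#'
#' @param x Signal vector (one analysis window).
#' @param fs Sampling rate, Hz.
#' @param beats A [beat_series()] with times relative to `x`'s start.
#' @param guard_s Margin excluded next to the beats bounding the gap
#'   (default 0.4 s), so the bounding QRS complexes and their T/P waves do
#'   not contribute to the swing.
#' @return Swing (max - min) of the signal inside the longest gap; 0 for a
#'   constant gap.
#' @export
blank_area_swing <- function(x, fs, beats, guard_s = 0.4) {
  dur <- length(x) / fs
  t <- accepted_beats(beats)$times
  t <- t[t >= 0 & t <= dur]
  edges <- c(0, t, dur)
  gaps <- diff(edges)
  j <- which.max(gaps)
  lo <- edges[j] + if (j > 1) guard_s else 0            # beat on the left
  hi <- edges[j + 1] - if (j < length(edges) - 1) guard_s else 0
  i0 <- max(1L, round(lo * fs) + 1L)
  i1 <- min(length(x), round(hi * fs))
  if (i0 >= i1) return(0)
  seg <- x[i0:i1]
  max(seg) - min(seg)
}

#' Spectral features for fibrillation analysis
#'
#' Mean frequency, median frequency and maximum-power-to-total-power ratio
#' of the tapered (Hann), mean-removed periodogram restricted to a band
#' (default 0.5-15 Hz).  Fibrillatory waveforms concentrate power near a
#' single low frequency, giving a high max-power ratio; organized rhythms
#' spread power across many QRS harmonics.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param band `c(low, high)` Hz band analyzed.
#' @param mask Optional validity mask; the longest unmasked run is used.
#' @param min_duration_s Minimum usable signal, seconds.
#' @return Named list `mean_freq`, `median_freq`, `max_power_ratio`
#'   (all `NA` on insufficient data).
#' @export
spectral_features <- function(x, fs,
                              band = default_config()$features$spectral_band_hz,
                              mask = NULL, min_duration_s = 4) {
  miss <- list(mean_freq = NA_real_, median_freq = NA_real_,
               max_power_ratio = NA_real_)
  x <- .longest_unmasked(x, mask)
  n <- length(x)
  if (n < min_duration_s * fs) return(miss)
  x0 <- x - mean(x)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
  X <- stats::fft(x0 * taper)
  nf <- floor(n / 2)
  P <- Mod(X[2:(nf + 1)])^2
  f <- (1:nf) * fs / n
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel) || sum(P[sel]) == 0) return(miss)
  P <- P[sel]; f <- f[sel]
  tot <- sum(P)
  cum <- cumsum(P) / tot
  # peak mass over the peak bin plus its immediate neighbors, so the Hann
  # taper's 3-bin spread of a pure tone still reads as one line
  jmax <- which.max(P)
  peak <- sum(P[max(1, jmax - 1):min(length(P), jmax + 1)])
  list(mean_freq = sum(f * P) / tot,
       median_freq = f[which(cum >= 0.5)[1]],
       max_power_ratio = peak / tot)
}

#' RR-interval and heart-rate run features
#'
#' Rate statistics over the accepted beats of an analysis window.  The rate
#' of an n-beat run is `60 * (n - 1) / (t_n - t_1)` bpm.  `max_rr_s`
#' includes the window-edge gaps (edge-to-first-beat and last-beat-to-edge),
#' so a beat-free window yields the window length — the behavior the
#' asystole features rely on.  Run lengths mirror the alarm definitions:
#' 5 beats (bradycardia), 17 beats (tachycardia), 4 beats (the bradycardia
#' verification rule), and maximal ventricular runs (VT).
#'
#' @param beats A [beat_series()]; rejected beats are excluded.
#' @param window `c(start, end)` seconds of the analysis window.
#' @return Named list: `max_rr_s`, `min_hr_5beat_bpm`, `max_hr_17beat_bpm`,
#'   `slowest_4beat_bpm`, `vt_run_max_len`, `vt_run_max_rate_bpm`.  Run
#'   features are `NA` when fewer beats than the run length exist
#'   (`vt_run_max_len` is 0 with no ventricular beats).
#' @export
rr_hr_features <- function(beats, window) {
  b <- accepted_beats(window_beats(beats, window))
  t <- b$times
  run_stat <- function(k, fun) {
    nb <- length(t)
    if (nb < k) return(NA_real_)
    i <- seq_len(nb - k + 1)
    fun(60 * (k - 1) / (t[i + k - 1] - t[i]))
  }
  vt_len <- 0; vt_rate <- NA_real_
  if (any(b$ventricular)) {
    r <- rle(b$ventricular)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    vt_len <- max(r$lengths[runs])
    rates <- numeric(0)
    for (j in runs[r$lengths[runs] >= 2]) {
      rt <- t[starts[j]:ends[j]]
      rates <- c(rates, 60 * (length(rt) - 1) / (rt[length(rt)] - rt[1]))
    }
    if (length(rates)) vt_rate <- max(rates)
  }
  list(max_rr_s = if (length(t)) max(diff(c(window[1], t, window[2])))
                  else diff(window),
       min_hr_5beat_bpm = run_stat(5, min),
       max_hr_17beat_bpm = run_stat(17, max),
       slowest_4beat_bpm = run_stat(4, min),
       vt_run_max_len = vt_len,
       vt_run_max_rate_bpm = vt_rate)
}

# mean width (s) of the QRS-band envelope above half its beat-local max;
# wide for ventricular complexes
env_width_mean <- function(beats, env, fs) {
  b <- accepted_beats(beats)
  if (!length(b$times)) return(NA_real_)
  eq <- env$envelopes[["qrs"]]
  half <- round(0.35 * fs)
  widths <- vapply(b$times, function(bt) {
    c0 <- round(bt * fs) + 1L
    lo <- max(1L, c0 - half); hi <- min(length(eq), c0 + half)
    seg <- eq[lo:hi]
    pk <- max(seg)
    if (pk <= 0) return(NA_real_)
    above <- seg > pk / 2
    ci <- min(max(c0 - lo + 1L, 1L), length(seg))
    if (!above[ci]) ci <- which.max(seg)
    l <- ci; while (l > 1 && above[l - 1]) l <- l - 1
    r <- ci; while (r < length(seg) && above[r + 1]) r <- r + 1
    (r - l + 1) / fs
  }, 0)
  widths <- widths[is.finite(widths)]
  if (!length(widths)) return(NA_real_)
  mean(widths)
}

# ---------------------------------------------------------------------------
# Feature registry
# ---------------------------------------------------------------------------

CHANNEL_ROLES <- c("ecg1", "ecg2", "ppg", "abp")

.base_block <- c("sqi_correlation", "sqi_peak_stability", "sqi_sharpness",
                 "sqi_periodicity", "swing_min", "swing_max", "swing_mean")

#' Feature registry per arrhythmia type
#'
#' Every available channel contributes a signal-quality block (template
#' correlation, peak-height stability, sharpness, periodicity) and a swing
#' block; each arrhythmia adds the features matching its definition:
#' asystole — maximum RR interval and blank-area swing; bradycardia —
#' minimum 5-beat heart rate and slowest 4-beat rate; tachycardia — maximum
#' 17-beat heart rate; ventricular fibrillation — spectral features on the
#' ECG leads; ventricular tachycardia — ventricular-run statistics and
#' envelope width on the ECG leads.
#'
#' @param arrhythmia Alarm type.
#' @return Character vector of feature names, `<role>_<feature>`.
#' @export
feature_registry <- function(arrhythmia) {
  arrhythmia <- match.arg(arrhythmia, ARRHYTHMIA_TYPES)
  per_role <- lapply(CHANNEL_ROLES, function(role) {
    extra <- switch(arrhythmia,
      ASYSTOLE    = c("max_rr", "blank_area_swing"),
      BRADYCARDIA = c("min_hr_5beat", "slowest_4beat"),
      TACHYCARDIA = c("max_hr_17beat"),
      VFIB        = if (role %in% c("ecg1", "ecg2"))
                      c("mean_freq", "median_freq", "max_power_ratio") else character(0),
      VTACH       = if (role %in% c("ecg1", "ecg2"))
                      c("vt_run_max_len", "vt_run_max_rate", "env_width_mean")
                    else character(0))
    paste0(role, "_", c(.base_block, extra))
  })
  unlist(per_role)
}

# map channels of a record to roles ecg1/ecg2/ppg/abp
channel_roles <- function(record) {
  kinds <- vapply(record$channels, function(ch) ch$kind, "")
  roles <- stats::setNames(rep(NA_character_, length(kinds)),
                           vapply(record$channels, function(ch) ch$name, ""))
  e <- which(kinds == "ECG")
  if (length(e) >= 1) roles[e[1]] <- "ecg1"
  if (length(e) >= 2) roles[e[2]] <- "ecg2"
  p <- which(kinds == "PPG")
  if (length(p) >= 1) roles[p[1]] <- "ppg"
  a <- which(kinds == "ABP")
  if (length(a) >= 1) roles[a[1]] <- "abp"
  roles
}

#' Extract the per-alarm feature vector(s)
#'
#' Assembles the registry features for one record over its arrhythmia's
#' analysis window.  For a true ventricular-fibrillation alarm in training
#' mode the extraction runs four times, with windows starting at the end of
#' seconds 293-296 (each running to the alarm), because the fibrillation
#' onset may fall anywhere within 10 s of the alarm; every other record
#' contributes exactly one row.  Channels that are absent or fully masked
#' yield missing values for their features.
#'
#' @param record An [alarm_record()].
#' @param beats Named list of [beat_series()] per channel name, times in
#'   record coordinates.
#' @param masks Named list of validity masks per channel
#'   ([build_validity_mask()]), or `NULL`.
#' @param env Named list of [estimate_envelopes()] per ECG channel computed
#'   on the analysis segment, with attribute `"offset_s"` giving the
#'   segment start (as produced by [process_record()]); or `NULL`.
#' @param cfg Configuration list.
#' @param training Logical; enables the true-VF window augmentation.
#' @return A `feature_table` with one row per extraction window.
#' @export
extract_features <- function(record, beats, masks = NULL, env = NULL,
                             cfg = default_config(), training = FALSE) {
  arr <- record$arrhythmia
  win <- cfg$features$windows[[arr]]
  windows <- list(win)
  if (arr == "VFIB" && training && record$label == "TRUE_ALARM")
    windows <- lapply(cfg$features$vf_augment_starts_s,
                      function(s) c(s, record$alarm_time_s))
  registry <- feature_registry(arr)
  roles <- channel_roles(record)
  rows <- lapply(windows, function(w)
    .extract_one_window(record, beats, masks, env, w, arr, registry, roles, cfg))
  df <- do.call(rbind, rows)
  df <- cbind(data.frame(record_id = record$record_id,
                         window_start = vapply(windows, `[`, 0, 1),
                         label = record$label,
                         stringsAsFactors = FALSE), df)
  new_feature_table(df, arrhythmia = arr)
}

.extract_one_window <- function(record, beats, masks, env, window, arr,
                                registry, roles, cfg) {
  fs <- record$fs
  out <- stats::setNames(as.list(rep(NA_real_, length(registry))), registry)
  i0 <- round(window[1] * fs) + 1L
  i1 <- min(record$n_samples, round(window[2] * fs))
  for (ci in seq_along(record$channels)) {
    ch <- record$channels[[ci]]
    role <- roles[ci]
    if (is.na(role)) next
    xw <- ch$samples[i0:i1]
    mw <- if (!is.null(masks[[ch$name]])) masks[[ch$name]][i0:i1] else NULL
    if (!is.null(mw) && !any(mw)) next
    if (ch$kind == "ECG")
      xw <- remove_baseline(xw, fs, cfg$preprocess$baseline_order)
    b <- beats[[ch$name]]
    if (is.null(b)) b <- beat_series(numeric(0))
    bw <- window_beats(b, window)
    bl <- shift_beats(bw, -window[1])   # beat times relative to the window
    set <- function(name, value) {
      key <- paste0(role, "_", name)
      if (key %in% registry && length(value) == 1)
        out[[key]] <<- as.numeric(value)
    }
    set("sqi_correlation", sqi_correlation(xw, fs, bl,
                                           cfg$features$template_half_window_s))
    set("sqi_peak_stability", sqi_peak_height_stability(bl,
                                                        cfg$features$stability_band))
    set("sqi_sharpness", sqi_sharpness(xw, fs, bl,
                                       cfg$features$sharpness_half_window_s))
    set("sqi_periodicity", sqi_periodicity(xw, fs, mw,
                                           cfg$features$periodicity_lag_s))
    sw <- swing_features(xw, fs, cfg$features$swing_sub_window_s, mw)
    set("swing_min", sw$swing_min)
    set("swing_max", sw$swing_max)
    set("swing_mean", sw$swing_mean)
    rr <- rr_hr_features(b, window)
    set("max_rr", rr$max_rr_s)
    set("min_hr_5beat", rr$min_hr_5beat_bpm)
    set("slowest_4beat", rr$slowest_4beat_bpm)
    set("max_hr_17beat", rr$max_hr_17beat_bpm)
    set("vt_run_max_len", rr$vt_run_max_len)
    set("vt_run_max_rate", rr$vt_run_max_rate_bpm)
    set("blank_area_swing", blank_area_swing(xw, fs, bl))
    sp <- spectral_features(xw, fs, cfg$features$spectral_band_hz, mw)
    set("mean_freq", sp$mean_freq)
    set("median_freq", sp$median_freq)
    set("max_power_ratio", sp$max_power_ratio)
    if (!is.null(env[[ch$name]])) {
      off <- attr(env[[ch$name]], "offset_s")
      if (is.null(off)) off <- 0
      set("env_width_mean",
          env_width_mean(shift_beats(bw, -off), env[[ch$name]], fs))
    }
  }
  as.data.frame(out, check.names = FALSE)
}

# ---------------------------------------------------------------------------
# feature_table container
# ---------------------------------------------------------------------------

META_COLUMNS <- c("record_id", "window_start", "label")

#' Construct a feature table
#'
#' A rectangular per-alarm feature table: provenance columns `record_id`,
#' `window_start`, `label`, then one numeric column per feature.  All rows
#' belong to one arrhythmia type; a true-VF alarm may contribute up to 4
#' rows, every other record exactly one.
#'
#' @param df Data frame with the meta columns and feature columns.
#' @param arrhythmia Alarm type the table serves.
#' @return Object of classes `feature_table` and `data.frame`.
#' @export
new_feature_table <- function(df, arrhythmia) {
  stopifnot(all(META_COLUMNS %in% names(df)))
  nms <- names(df)[!names(df) %in% META_COLUMNS]
  if (anyDuplicated(nms))
    stop("duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(df, arrhythmia = match.arg(arrhythmia, ARRHYTHMIA_TYPES),
            class = c("feature_table", "data.frame"))
}

#' @rdname new_feature_table
#' @param table A `feature_table`.
#' @export
feature_names <- function(table) setdiff(names(table), META_COLUMNS)

#' @rdname new_feature_table
#' @export
feature_matrix <- function(table) {
  as.data.frame(table)[, feature_names(table), drop = FALSE]
}

#' Bind feature tables of the same arrhythmia
#' @param ... `feature_table` objects.
#' @return A combined `feature_table`.
#' @export
bind_feature_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "feature_table")) tabs <- tabs[[1]]
  arr <- unique(vapply(tabs, function(t) attr(t, "arrhythmia"), ""))
  stopifnot(length(arr) == 1)
  new_feature_table(do.call(rbind, lapply(tabs, as.data.frame)), arr)
}
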