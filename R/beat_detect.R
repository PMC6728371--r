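#' Slope sum function
#'
#' Windowed sum of positive first differences over a trailing (causal)
#' window; emphasizes the rising edge of pulse waves.  `y[i]` sums
#' `max(x[j] - x[j-1], 0)` over the `w` differences ending at sample `i`,
#' where `w = round(window_s * fs)`; leading partial windows are allowed.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 128 ms).
#' @return Numeric vector of the same length as `x`; non-negative.
#' @export
ssf <- function(x, fs, window_s = 0.128) {
  w <- max(1L, round(window_s * fs))
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- pmax(diff(x), 0)
  cs <- c(0, cumsum(dx))            # cs[i+1] = sum of first i diffs
  i <- seq_len(n)
  lo <- pmax(i - 1L - w, 0L)
  cs[i] - cs[lo + 1L]               # y[i] = sum of diffs (i-w-1, i-1]
}

# ---------------------------------------------------------------------------
# Dyadic (a trous) wavelet transform with a quadratic-spline-like wavelet.
# Detail coefficients approximate the smoothed derivative of the signal at
# scale 2^k, so an R peak appears as a positive-negative modulus-maxima pair
# with a zero crossing at the peak.
# ---------------------------------------------------------------------------

.upsample_filter <- function(f, up) {
  if (up == 1) return(f)
  out <- rep(0, (length(f) - 1) * up + 1)
  out[seq(1, length(out), by = up)] <- f
  out
}

# causal convolution with edge replication, then shift left to undo the
# filter group delay so coefficients align with the input samples
.conv_aligned <- function(x, f, delay) {
  n <- length(x)
  pad <- length(f)
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  y <- stats::filter(xp, f, method = "convolution", sides = 1)
  y <- as.numeric(y)
  sh <- pad + round(delay)
  out <- y[(sh + 1):(sh + n)]
  out[is.na(out)] <- 0
  out
}

#' Dyadic wavelet transform for QRS delineation
#'
#' Computes detail coefficients at scales `2^1 ... 2^n_scales` with the
#' a-trous algorithm (low-pass `[1,3,3,1]/8`, high-pass `[2,-2]`), delays
#' compensated so the zero crossing of a modulus-maxima pair sits at the
#' waveform peak.
#'
#' @param x Numeric vector.
#' @param n_scales Number of dyadic scales.
#' @return Matrix `length(x) x n_scales` of detail coefficients.
#' @keywords internal
dyadic_wt <- function(x, n_scales = 4L) {
  h0 <- c(1, 3, 3, 1) / 8
  g0 <- c(2, -2)
  n <- length(x)
  W <- matrix(0, n, n_scales)
  a <- x
  delay_a <- 0
  for (k in seq_len(n_scales)) {
    up <- 2^(k - 1)
    g <- .upsample_filter(g0, up)
    h <- .upsample_filter(h0, up)
    W[, k] <- .conv_aligned(a, g, delay_a + up / 2)
    a <- .conv_aligned(a, h, 1.5 * up)   # aligned approximation for next level
    # delays already compensated stage by stage, so delay_a stays 0
  }
  W
}

# Parabolic (three-point) interpolation of an extremum for sub-sample timing.
.refine_extremum <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(i)
  den <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (den == 0) return(i)
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / den
  if (abs(delta) > 1) delta <- 0
  i + delta
}

# Core modulus-maxima pair detector shared by the QRS and pulse-onset
# detectors.  Finds zero crossings of the detail signal at `scale` flanked
# by opposite-sign modulus maxima above an adaptive threshold; enforces a
# refractory period; searches back at half threshold inside long gaps.
.detect_peaks_wt <- function(x, fs, scale = 2L, cfg = default_config()$detect) {
  n <- length(x)
  if (n < 16) return(list(idx = numeric(0), times = numeric(0)))
  W <- dyadic_wt(x, max(scale, 2L))
  w <- W[, scale]
  if (max(abs(w)) == 0) return(list(idx = numeric(0), times = numeric(0)))
  thr <- cfg$threshold_rms_factor * sqrt(mean(w^2))
  m <- max(2L, round(cfg$pair_window_s * fs))
  refr <- cfg$refractory_s

  find_candidates <- function(threshold, lo = 1L, hi = n) {
    seg <- lo:hi
    ws <- w[seg]
    s <- sign(ws)
    zc <- which(s[-length(s)] > 0 & s[-1] <= 0)  # + -> - crossings
    zc2 <- which(s[-length(s)] < 0 & s[-1] >= 0) # - -> + crossings (inverted peaks)
    cands <- list()
    for (z in zc) {
      a <- max(ws[max(1, z - m):z]); b <- min(ws[(z + 1):min(length(ws), z + m)])
      if (a > threshold && -b > threshold)
        cands[[length(cands) + 1]] <- c(i = seg[1] + z - 1, str = min(a, -b),
                                        pol = 1)
    }
    for (z in zc2) {
      a <- min(ws[max(1, z - m):z]); b <- max(ws[(z + 1):min(length(ws), z + m)])
      if (-a > threshold && b > threshold)
        cands[[length(cands) + 1]] <- c(i = seg[1] + z - 1, str = min(-a, b),
                                        pol = -1)
    }
    if (!length(cands)) return(NULL)
    do.call(rbind, cands)
  }

  cands <- find_candidates(thr)
  if (is.null(cands)) return(list(idx = numeric(0), times = numeric(0)))
  cands <- cands[order(cands[, "i"]), , drop = FALSE]

  apply_refractory <- function(cands) {
    keep <- rep(TRUE, nrow(cands))
    last <- 1L
    for (i in seq_len(nrow(cands))[-1]) {
      if ((cands[i, "i"] - cands[last, "i"]) / fs < refr) {
        if (cands[i, "str"] > cands[last, "str"]) {
          keep[last] <- FALSE; last <- i
        } else keep[i] <- FALSE
      } else last <- i
    }
    cands[keep, , drop = FALSE]
  }
  cands <- apply_refractory(cands)

  # search-back: rescan long RR gaps at half threshold
  if (nrow(cands) >= 3) {
    rr <- diff(cands[, "i"]) / fs
    med <- stats::median(rr)
    gaps <- which(rr > cfg$searchback_factor * med)
    extra <- NULL
    for (g in gaps) {
      lo <- cands[g, "i"] + round(refr * fs)
      hi <- cands[g + 1, "i"] - round(refr * fs)
      if (hi - lo < m) next
      found <- find_candidates(thr / 2, lo, hi)
      if (!is.null(found)) extra <- rbind(extra, found)
    }
    if (!is.null(extra)) {
      cands <- rbind(cands, extra)
      cands <- cands[order(cands[, "i"]), , drop = FALSE]
      cands <- apply_refractory(cands)
    }
  }

  # localize the waveform extremum near each zero crossing, sub-sample refined
  half <- max(2L, round(0.04 * fs))
  idx <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    z <- cands[i, "i"]
    lo <- max(1, z - half); hi <- min(n, z + half)
    seg <- x[lo:hi]
    j <- if (cands[i, "pol"] > 0) which.max(seg) else which.min(seg)
    idx[i] <- lo + j - 1
    idx[i] <- lo - 1 + .refine_extremum(seg, j)
  }
  o <- order(idx)
  idx <- idx[o]
  # dedupe anything the refinement collapsed
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) / fs >= refr / 2)]
  list(idx = idx, times = (idx - 1) / fs)
}

#' Wavelet-transform QRS detection
#'
#' Multiscale (dyadic, quadratic-spline-like) wavelet detector: R peaks are
#' zero crossings between opposite-sign modulus maxima at scale `2^2`,
#' thresholded adaptively from the detail-coefficient RMS, with a 0.2-s
#' refractory period and a half-threshold search-back inside long RR gaps.
#' Thresholds are relative, so detection is invariant to positive amplitude
#' scaling and constant offsets.
#'
#' @param ecg Baseline-removed ECG vector.
#' @param fs Sampling rate in Hz; at least 100.
#' @param cfg Detection constants, `default_config()$detect`.
#' @param mask Optional validity mask; beats inside masked spans are dropped,
#'   and an all-masked input yields an empty series.
#' @param channel Channel name recorded in the result.
#' @return A [beat_series()] of R-peak times (seconds, sub-sample refined)
#'   and amplitudes.
#' @export
detect_qrs <- function(ecg, fs, cfg = default_config()$detect, mask = NULL,
                       channel = NA_character_) {
  if (fs < 100) stop("unsupported sampling rate ", fs, " Hz (need >= 100)")
  if (!is.null(mask) && !any(mask))
    return(beat_series(numeric(0), detector = "WAVELET_QRS", channel = channel))
  det <- .detect_peaks_wt(ecg, fs, scale = cfg$qrs_scale, cfg = cfg)
  keep <- .unmasked_beats(det$idx, mask)
  idx <- det$idx[keep]
  beat_series(det$times[keep],
              amplitudes = ecg[pmin(pmax(round(idx), 1), length(ecg))],
              detector = "WAVELET_QRS", channel = channel)
}

.unmasked_beats <- function(idx, mask) {
  if (is.null(mask) || !length(idx)) return(rep(TRUE, length(idx)))
  mask[pmin(pmax(round(idx), 1), length(mask))]
}

#' Pulse-onset detection by double slope sum function
#'
#' Computes `S2 = SSF(SSF(x))` (no low-pass prefiltering) and finds the peaks
#' of `S2` with the wavelet peak detector; each peak marks the upstroke of
#' one pulse in the original BP/PPG signal.  Onset times are the `S2` peak
#' times minus a fixed group-delay correction (one SSF window by default).
#' Because the SSF responds only to local positive slopes, detection is
#' insensitive to baseline wander.
#'
#' @param x BP or PPG vector.
#' @param fs Sampling rate, Hz.
#' @param cfg Detection constants, `default_config()$detect`.
#' @param mask Optional validity mask (see [detect_qrs()]).
#' @param channel Channel name recorded in the result.
#' @return A [beat_series()] of pulse-onset times with amplitudes read from
#'   the original signal.
#' @export
detect_pulse_onsets <- function(x, fs, cfg = default_config()$detect,
                                mask = NULL, channel = NA_character_) {
  if (!is.null(mask) && !any(mask))
    return(beat_series(numeric(0), detector = "DOUBLE_SSF", channel = channel))
  s2 <- ssf(ssf(x, fs, cfg$ssf_window_s), fs, cfg$ssf_window_s)
  det <- .detect_peaks_wt(s2, fs, scale = cfg$pulse_scale, cfg = cfg)
  delay <- if (is.null(cfg$pulse_delay_s)) cfg$ssf_window_s else cfg$pulse_delay_s
  times <- det$times - delay
  keep <- times >= 0 & .unmasked_beats(times * fs + 1, mask)
  times <- times[keep]
  idx <- pmin(pmax(round(times * fs) + 1, 1), length(x))
  beat_series(times, amplitudes = x[idx], detector = "DOUBLE_SSF",
              channel = channel)
}

#' Amplitude envelopes in physiological bands
#'
#' Band-pass filters the signal (zero-phase Butterworth), rectifies, and
#' smooths with a short moving average, yielding one non-negative envelope
#' per band.  Default bands: low 0.5-6 Hz (P/T-wave energy), QRS 5-25 Hz,
#' high 30-90 Hz (pacing spikes, high-frequency artifact).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param bands Named list of `c(low, high)` Hz pairs within `(0, fs/2)`.
#' @param smooth_s Moving-average length in seconds.
#' @return Object of class `envelope_set`: list of envelopes plus the band
#'   edges.
#' @export
estimate_envelopes <- function(x, fs,
                               bands = default_config()$detect$bands,
                               smooth_s = default_config()$detect$envelope_smooth_s) {
  env <- list()
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] || b[2] >= fs / 2)
      stop("invalid band '", nm, "': must satisfy 0 < low < high < fs/2")
    bf <- signal::butter(3, b / (fs / 2), type = "pass")
    y <- abs(signal::filtfilt(bf, x))
    w <- max(1L, round(smooth_s * fs))
    kern <- rep(1 / w, w)
    sm <- stats::filter(c(rep(y[1], w), y, rep(y[length(y)], w)), kern,
                        sides = 2)
    env[[nm]] <- pmax(as.numeric(sm[(w + 1):(w + length(y))]), 0)
  }
  structure(list(envelopes = env, bands = bands, fs = fs),
            class = "envelope_set")
}

.env_at <- function(env, band, times) {
  e <- env$envelopes[[band]]
  idx <- pmin(pmax(round(times * env$fs) + 1L, 1L), length(e))
  e[idx]
}
#' Reject false R-peak detections with amplitude envelopes
#'
#' Two failure modes of QRS detection on monitor ECGs are screened using the
#' band envelopes: high-frequency pacing spikes (high-band envelope at the
#' fiducial exceeding `kappa_pacing` times the QRS-band envelope) and T-wave
#' over-sensing (QRS-band envelope below `kappa_twave` times the median
#' QRS-band envelope of the surviving beats).
#'
#' @param beats A [beat_series()].
#' @param env An [estimate_envelopes()] result on the same channel.
#' @param cfg Detection constants.
#' @return The beat series with `rejected` codes filled in
#'   (`PACING_SPIKE`, `T_WAVE`, `NONE`); beat order unchanged.
#' @export
reject_false_peaks <- function(beats, env, cfg = default_config()$detect) {
  if (!length(beats$times)) return(beats)
  eh <- .env_at(env, "high", beats$times)
  eq <- .env_at(env, "qrs", beats$times)
  rej <- beats$rejected
  pace <- eh > cfg$kappa_pacing * eq & rej == "NONE"
  rej[pace] <- "PACING_SPIKE"
  ok <- rej == "NONE"
  if (any(ok)) {
    med <- stats::median(eq[ok])
    tw <- ok & eq < cfg$kappa_twave * med
    rej[tw] <- "T_WAVE"
  }
  beats$rejected <- rej
  beats
}

#' Flag wide ventricular complexes
#'
#' A beat is marked ventricular when its QRS-band envelope stays above half
#' its beat-local maximum for longer than `vt_width_s` (default 140 ms) and
#' its high-band content at the fiducial is low relative to the QRS band —
#' i.e. the complex is wide and smooth, as in ventricular tachycardia.
#'
#' @param beats A [beat_series()] on an ECG channel.
#' @param env An [estimate_envelopes()] result for that channel.
#' @param fs Sampling rate, Hz.
#' @param cfg Detection constants.
#' @return The beat series with the `ventricular` flags filled in (rejected
#'   beats are never flagged).
#' @export
flag_ventricular <- function(beats, env, fs, cfg = default_config()$detect) {
  if (!length(beats$times)) return(beats)
  eq <- env$envelopes[["qrs"]]
  eh <- .env_at(env, "high", beats$times)
  eqb <- .env_at(env, "qrs", beats$times)
  half <- round(0.35 * fs)
  vent <- logical(length(beats$times))
  for (i in seq_along(beats$times)) {
    if (beats$rejected[i] != "NONE") next
    c0 <- round(beats$times[i] * fs) + 1L
    lo <- max(1L, c0 - half); hi <- min(length(eq), c0 + half)
    seg <- eq[lo:hi]
    pk <- max(seg)
    if (pk <= 0) next
    above <- seg > pk / 2
    # width of the contiguous above-half-max run containing the fiducial
    ci <- min(max(c0 - lo + 1L, 1L), length(seg))
    if (!above[ci]) ci <- which.max(seg)
    l <- ci; while (l > 1 && above[l - 1]) l <- l - 1
    r <- ci; while (r < length(seg) && above[r + 1]) r <- r + 1
    width_s <- (r - l + 1) / fs
    vent[i] <- width_s > cfg$vt_width_s &&
      eh[i] < cfg$vt_high_ratio * eqb[i]
  }
  beats$ventricular <- vent
  beats
}
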