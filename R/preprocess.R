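#' Detect flat-line segments
#'
#' A signal window contains a flat line when it holds a constant value for at
#' least `min_duration_s` seconds (default 2 s), indicating probe
#' disconnection.  Constancy means successive samples differ by at most `tol`
#' (default 0: exactly repeated samples, which is what a disconnected probe
#' produces in raw ADC units).
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param min_duration_s Minimum duration of a constant run, seconds.
#' @param tol Maximum absolute difference between successive samples counted
#'   as constant.
#' @return A two-column matrix of half-open, 0-based sample intervals
#'   `[start, end)`, one row per maximal flat run; zero rows when none.
#' @export
detect_flat_line <- function(samples, fs, min_duration_s = 2.0, tol = 0) {
  n <- length(samples)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (n < 2) return(empty)
  flat <- abs(diff(samples)) <= tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_run <- ceiling(min_duration_s * fs - 1e-9)  # samples in the run
  keep <- r$values & (r$lengths + 1L) >= min_run
  if (!any(keep)) return(empty)
  # run of k TRUE diffs spans k+1 samples: [starts-1, ends+1) 0-based
  out <- cbind(start = starts[keep] - 1L, end = ends[keep] + 1L)
  out
}

#' Remove baseline wander from an ECG segment
#'
#' Subtracts the least-squares polynomial fit of the given order (default 5)
#' over the analysis window.  The operation is linear in its input and
#' annihilates any polynomial of degree up to `order`.
#'
#' @param ecg Numeric vector (one analysis window).
#' @param fs Sampling rate in Hz (unused by the fit, kept for interface
#'   symmetry).
#' @param order Polynomial order of the baseline model.
#' @return The detrended segment, same length as `ecg`.
#' @export
remove_baseline <- function(ecg, fs = NULL, order = 5L) {
  n <- length(ecg)
  if (n < order + 1)
    stop("window too short for baseline removal: ", n,
         " samples < order + 1 = ", order + 1)
  if (stats::sd(ecg) == 0) return(rep(0, n))
  tt <- seq_len(n)
  X <- cbind(1, stats::poly(tt, degree = order))
  fit <- stats::lm.fit(X, ecg)
  as.numeric(fit$residuals)
}

#' Per-beat abnormality screening of an arterial blood pressure waveform
#'
#' Applies the classical ABP signal-abnormality criteria on each detected
#' beat (the segment from one pulse onset to the next): systolic above
#' 300 mmHg, diastolic below 20 mmHg, mean pressure outside 30-200 mmHg,
#' pulse pressure below 20 mmHg, mean negative slope steeper than
#' -40 mmHg per 100 ms, and beat-to-beat systolic or diastolic jumps above
#' 20 mmHg.  The heart-rate-range and beat-period-change criteria are
#' implemented but disabled by default.
#'
#' @param bp Numeric ABP vector in mmHg.
#' @param fs Sampling rate in Hz.
#' @param beats A [beat_series()] of pulse onsets detected on this channel.
#' @param cfg Criterion thresholds, `default_config()$preprocess$bp`.
#' @return Logical vector, one flag per beat (`TRUE` = abnormal); attribute
#'   `"reasons"` lists the criteria that fired per beat.  Empty when `beats`
#'   is empty.
#' @export
bp_abnormality <- function(bp, fs, beats, cfg = default_config()$preprocess$bp) {
  t <- accepted_beats(beats)$times
  nb <- length(t)
  if (nb == 0) return(stats::setNames(logical(0), character(0)))
  idx <- pmin(pmax(round(t * fs) + 1L, 1L), length(bp))
  # beat segment i: [onset_i, onset_{i+1}); last beat extends one median period
  med_ibi <- if (nb > 1) stats::median(diff(t)) else 1
  seg_end <- c(idx[-1] - 1L, pmin(length(bp), idx[nb] + round(med_ibi * fs)))
  sys <- dia <- mp <- pp <- nslope <- numeric(nb)
  for (i in seq_len(nb)) {
    seg <- bp[idx[i]:seg_end[i]]
    sys[i] <- max(seg); dia[i] <- min(seg); mp[i] <- mean(seg)
    pp[i] <- sys[i] - dia[i]
    d <- diff(seg)
    neg <- d[d < 0]
    nslope[i] <- if (length(neg)) mean(neg) * fs else 0
  }
  period <- c(NA, diff(t))
  hr <- 60 / period
  reasons <- vector("list", nb)
  flag <- logical(nb)
  add <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    flag <<- flag | cond
    for (i in which(cond)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(sys > cfg$systolic_max_mmHg, "SYS_HIGH")
  add(dia < cfg$diastolic_min_mmHg, "DIA_LOW")
  add(mp < cfg$map_min_mmHg | mp > cfg$map_max_mmHg, "MAP_RANGE")
  add(pp < cfg$pulse_pressure_min_mmHg, "PP_LOW")
  add(nslope < cfg$neg_slope_max_mmHg_per_s, "NEG_SLOPE")
  add(c(NA, abs(diff(sys))) > cfg$delta_sys_max_mmHg, "DELTA_SYS")
  add(c(NA, abs(diff(dia))) > cfg$delta_dia_max_mmHg, "DELTA_DIA")
  if (isTRUE(cfg$use_hr_criterion))
    add(hr < cfg$hr_range_bpm[1] | hr > cfg$hr_range_bpm[2], "HR_RANGE")
  if (isTRUE(cfg$use_period_criterion))
    add(c(NA, abs(diff(period))) > cfg$delta_period_max_s, "DELTA_PERIOD")
  attr(flag, "reasons") <- reasons
  flag
}

#' Build per-channel validity masks for an alarm record
#'
#' Combines the gates that suppress downstream analysis: flat-line runs on
#' every channel, and (when pulse onsets are supplied) abnormal-beat spans on
#' ABP channels.  Downstream feature operations skip masked spans.
#'
#' @param record An [alarm_record()].
#' @param beats Optional named list of [beat_series()] per channel name, used
#'   for the ABP abnormality criteria.
#' @param cfg Configuration list, see [default_config()].
#' @return Named list (by channel name) of logical vectors (`TRUE` =
#'   analyzable) with attribute `"reasons"`: a data frame of invalid runs
#'   with columns `start`, `end` (0-based, half-open) and `reason`
#'   (`FLATLINE` or `ABNORMAL_BP`).
#' @export
build_validity_mask <- function(record, beats = NULL, cfg = default_config()) {
  out <- list()
  for (ch in record$channels) {
    mask <- rep(TRUE, length(ch$samples))
    runs <- data.frame(start = integer(0), end = integer(0),
                       reason = character(0))
    fl <- detect_flat_line(ch$samples, ch$fs,
                           cfg$preprocess$flat_min_duration_s,
                           cfg$preprocess$flat_tol)
    if (nrow(fl)) {
      for (r in seq_len(nrow(fl)))
        mask[(fl[r, 1] + 1):fl[r, 2]] <- FALSE
      runs <- rbind(runs, data.frame(start = fl[, 1], end = fl[, 2],
                                     reason = "FLATLINE"))
    }
    if (ch$kind == "ABP" && !is.null(beats[[ch$name]])) {
      b <- accepted_beats(beats[[ch$name]])
      if (length(b$times)) {
        flags <- bp_abnormality(ch$samples, ch$fs, b, cfg$preprocess$bp)
        idx <- pmin(pmax(round(b$times * ch$fs) + 1L, 1L), length(ch$samples))
        med_ibi <- if (length(b$times) > 1) stats::median(diff(b$times)) else 1
        ends <- c(idx[-1] - 1L,
                  pmin(length(ch$samples), idx[length(idx)] + round(med_ibi * ch$fs)))
        for (i in which(flags)) {
          mask[idx[i]:ends[i]] <- FALSE
          runs <- rbind(runs, data.frame(start = idx[i] - 1L, end = ends[i],
                                         reason = "ABNORMAL_BP"))
        }
      }
    }
    attr(mask, "reasons") <- runs
    out[[ch$name]] <- mask
  }
  out
}
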