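#' Specify a synthetic alarm record
#'
#' Builds the parameter list consumed by [generate_record()].  Defaults are
#' the study conditions used throughout the package's validation: 250 Hz,
#' 300-s records with the alarm at 300 s, two ECG leads plus one pulse
#' channel, a 75-bpm base rhythm with 2% RR jitter, light wideband noise and
#' slow baseline wander.  The `episode` describes the arrhythmia (or
#' near-alarm artifact) placed against that background; the noise block
#' carries the artifact processes that generate false alarms on real
#' monitors (artifact bursts, flat lines, pacing spikes).
#'
#' @param arrhythmia Alarm type raised at 300 s.
#' @param label `TRUE_ALARM` or `FALSE_ALARM` — the scenario the generator
#'   must realize (validated against the ground-truth annotator).
#' @param seed Integer seed; the record is a deterministic function of the
#'   full spec.
#' @param episode List describing the arrhythmia episode, or `NULL`:
#'   asystole `list(gap_s, gap_end_s)`; bradycardia/tachycardia
#'   `list(rate_bpm, n_beats)`; vtach `list(rate_bpm, n_beats)`;
#'   vfib `list(onset_s, freq_hz)`.
#' @param channels Channel names; kinds are inferred by [channel_kind()].
#' @param base_hr_bpm Background heart rate.
#' @param noise List: `white_sd`, `wander_amp`, `wander_freq_hz`,
#'   `flat_intervals` (list of `c(start, end)` seconds, per the first ECG),
#'   `bursts` (list of `list(at_s, dur_s, amp, band_hz, channel)`),
#'   `pacing_rate_hz`, `pacing_amp`, `ppg_noise_sd`.
#' @param fs,duration_s Sampling rate and record length.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(arrhythmia, label, seed,
                       episode = NULL,
                       channels = c("II", "V", "PLETH"),
                       base_hr_bpm = 75,
                       noise = list(),
                       fs = 250, duration_s = 300) {
  arrhythmia <- match.arg(arrhythmia, ARRHYTHMIA_TYPES)
  label <- match.arg(label, c("TRUE_ALARM", "FALSE_ALARM"))
  noise_def <- list(white_sd = 0.02, wander_amp = 0.08, wander_freq_hz = 0.25,
                    flat_intervals = list(), bursts = list(),
                    pacing_rate_hz = 0, pacing_amp = 1.8, ppg_noise_sd = 0)
  noise <- modify_list_deep(noise_def, noise)
  structure(list(arrhythmia = arrhythmia, label = label, seed = as.integer(seed),
                 episode = episode, channels = channels,
                 base_hr_bpm = base_hr_bpm, noise = noise, fs = fs,
                 duration_s = duration_s),
            class = "synth_spec")
}

# Ricker (negative second derivative of a Gaussian): a narrow version is the
# QRS template, a wide version the ventricular complex.
.ricker <- function(tt, sigma) (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))

.add_bump <- function(x, t0, fs, width_s, fun) {
  n <- length(x)
  i0 <- max(1L, floor((t0 - width_s) * fs) + 1L)
  i1 <- min(n, ceiling((t0 + width_s) * fs) + 1L)
  if (i0 > i1) return(x)
  tt <- ((i0:i1) - 1) / fs - t0
  x[i0:i1] <- x[i0:i1] + fun(tt)
  x
}

# beat schedule: background rhythm with the episode spliced in near the alarm
.build_beats <- function(spec) {
  fs <- spec$fs; dur <- spec$duration_s
  ibi <- 60 / spec$base_hr_bpm
  t <- seq(0.4, dur - 0.2, by = ibi)
  t <- t + stats::rnorm(length(t), sd = 0.02 * ibi)  # RR jitter
  t <- sort(t)
  vent <- rep(FALSE, length(t))
  ep <- spec$episode
  vf_interval <- NULL
  if (!is.null(ep)) {
    type <- spec$arrhythmia
    if (type == "ASYSTOLE") {
      gap_end <- if (is.null(ep$gap_end_s)) 299 else ep$gap_end_s
      keep <- t <= gap_end - ep$gap_s | t >= gap_end
      t <- t[keep]; vent <- vent[keep]
    } else if (type %in% c("BRADYCARDIA", "TACHYCARDIA", "VTACH")) {
      n_b <- ep$n_beats
      rate <- ep$rate_bpm
      span <- (n_b - 1) * 60 / rate
      end <- dur - 0.7
      run <- end - span + (seq_len(n_b) - 1) * 60 / rate
      keep <- t < run[1] - 0.6 * 60 / rate | t > end + 0.5
      t <- t[keep]; vent <- vent[keep]
      t <- c(t, run)
      vent <- c(vent, rep(type == "VTACH", n_b))
      o <- order(t); t <- t[o]; vent <- vent[o]
    } else if (type == "VFIB") {
      vf_interval <- c(ep$onset_s, dur)
      keep <- t < ep$onset_s | t > dur
      t <- t[keep]; vent <- vent[keep]
    }
  }
  list(times = t, ventricular = vent, vf_interval = vf_interval)
}

.ecg_wave <- function(beats, spec, lead_scale) {
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  x <- numeric(n)
  for (i in seq_along(beats$times)) {
    bt <- beats$times[i]
    if (beats$ventricular[i]) {
      x <- .add_bump(x, bt, fs, 0.25,
                     function(tt) 1.1 * .ricker(tt, 0.04))
    } else {
      x <- .add_bump(x, bt, fs, 0.12, function(tt) .ricker(tt, 0.02))
      x <- .add_bump(x, bt + 0.25, fs, 0.18,
                     function(tt) 0.18 * exp(-tt^2 / (2 * 0.05^2)))  # T
      x <- .add_bump(x, bt - 0.18, fs, 0.1,
                     function(tt) 0.08 * exp(-tt^2 / (2 * 0.03^2)))  # P
    }
  }
  if (!is.null(beats$vf_interval)) {
    iv <- beats$vf_interval
    i0 <- max(1L, round(iv[1] * fs) + 1L); i1 <- min(n, round(iv[2] * fs))
    tt <- ((i0:i1) - 1) / fs
    f <- spec$episode$freq_hz
    am <- 0.65 + 0.35 * sin(2 * pi * 0.5 * tt + stats::runif(1, 0, 2 * pi))
    ramp <- pmin((tt - iv[1]) / 0.5, 1)   # short transition into VF
    x[i0:i1] <- x[i0:i1] * (1 - ramp) +
      ramp * am * sin(2 * pi * f * (tt - iv[1]))
  }
  x * lead_scale
}

.pulse_wave <- function(onsets, n, fs, sys, dia, rise = 0.12, decay = 0.35) {
  x <- rep(dia, n)
  k <- length(onsets)
  if (!k) return(x)
  med <- if (k > 1) stats::median(diff(onsets)) else 0.8
  for (i in seq_len(k)) {
    t0 <- onsets[i]
    t1 <- if (i < k) onsets[i + 1] else t0 + med
    i0 <- round(t0 * fs) + 1L; i1 <- min(n, round(t1 * fs))
    if (i0 >= i1 || i0 < 1) next
    seg_t <- ((i0:i1) - 1) / fs - t0
    shape <- ifelse(seg_t < rise, 0.5 - 0.5 * cos(pi * pmin(seg_t / rise, 1)),
                    exp(-(seg_t - rise) / decay))
    x[i0:i1] <- dia + (sys - dia) * shape
  }
  x
}

.apply_noise <- function(x, spec, fs, kind, channel_name) {
  nz <- spec$noise
  n <- length(x)
  tt <- ((1:n) - 1) / fs
  scale <- if (kind == "ABP") 10 else 1   # noise amplitudes are ECG-scaled
  if (nz$white_sd > 0) x <- x + stats::rnorm(n, sd = nz$white_sd * scale)
  if (nz$wander_amp > 0 && kind == "ECG")
    x <- x + nz$wander_amp * sin(2 * pi * nz$wander_freq_hz * tt +
                                   stats::runif(1, 0, 2 * pi))
  if (kind == "PPG" && nz$ppg_noise_sd > 0)
    x <- x + stats::rnorm(n, sd = nz$ppg_noise_sd)
  for (b in nz$bursts) {
    if (!is.null(b$channel) && !identical(b$channel, channel_name)) next
    i0 <- max(1L, round((b$at_s - b$dur_s / 2) * fs))
    i1 <- min(n, round((b$at_s + b$dur_s / 2) * fs))
    if (i0 >= i1) next
    m <- i1 - i0 + 1
    band <- if (is.null(b$band_hz)) c(1, 40) else b$band_hz
    bf <- signal::butter(2, pmin(band / (fs / 2), 0.99), type = "pass")
    burst <- as.numeric(signal::filtfilt(bf, stats::rnorm(m + 2 * fs)))
    burst <- burst[(fs + 1):(fs + m)]
    burst <- burst / max(abs(burst), 1e-12) * b$amp
    taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
    x[i0:i1] <- x[i0:i1] + burst * taper * scale
  }
  if (nz$pacing_rate_hz > 0 && kind == "ECG") {
    times <- seq(0.3, n / fs - 0.3, by = 1 / nz$pacing_rate_hz)
    idx <- round(times * fs) + 1L
    x[idx] <- x[idx] + nz$pacing_amp * scale
  }
  if (kind == "ECG" && channel_name == spec$channels[1]) {
    for (iv in nz$flat_intervals) {
      i0 <- max(1L, round(iv[1] * fs) + 1L); i1 <- min(n, round(iv[2] * fs))
      if (i0 < i1) x[i0:i1] <- x[max(1L, i0 - 1L)]
    }
  }
  x
}

#' Generate a synthetic alarm record with exact ground truth
#'
#' Renders the waveforms described by a [synth_spec()]: ECG as a sum of
#' per-beat Ricker (Gaussian second-derivative) QRS templates with P/T
#' bumps, wide smooth complexes for ventricular beats, an
#' amplitude-modulated 4-7 Hz sinusoid for fibrillation; PPG/ABP as
#' asymmetric pulse waves triggered ~200 ms after each QRS (ABP in mmHg,
#' e.g. 120/80).  Noise processes (white noise, baseline wander, artifact
#' bursts, pacing spikes, flat lines) are applied per the spec.  The result
#' is bit-deterministic given the spec.
#'
#' The generated truth is validated: a `TRUE_ALARM` spec must yield a
#' qualifying episode overlapping the 10 s before the alarm, and a
#' `FALSE_ALARM` spec must not satisfy its alarm type's definition —
#' contradictory specs raise an error.
#'
#' @param spec A [synth_spec()].
#' @return List with elements `record` (an [alarm_record()]) and `truth`
#'   (class `ground_truth`: true beat times, ventricular flags, episode
#'   interval, per-arrhythmia verdicts).
#' @export
generate_record <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    fs <- spec$fs
    n <- round(spec$duration_s * fs)
    beats <- .build_beats(spec)
    kinds <- channel_kind(spec$channels)
    channels <- vector("list", length(spec$channels))
    ecg_i <- 0
    for (ci in seq_along(spec$channels)) {
      nm <- spec$channels[ci]; kind <- kinds[ci]
      if (kind == "ECG") {
        ecg_i <- ecg_i + 1
        x <- .ecg_wave(beats, spec, lead_scale = c(1, 0.75, 0.6)[ecg_i])
      } else {
        onsets <- beats$times + 0.2   # pulse transit delay
        onsets <- onsets[onsets < spec$duration_s]
        if (!is.null(beats$vf_interval))  # no effective output during VF
          onsets <- onsets[onsets < beats$vf_interval[1]]
        if (kind == "ABP") {
          x <- .pulse_wave(onsets, n, fs, sys = 120, dia = 80)
        } else {
          x <- .pulse_wave(onsets, n, fs, sys = 1, dia = 0)
        }
      }
      x <- .apply_noise(x, spec, fs, kind, nm)
      channels[[ci]] <- new_channel(nm, x, fs)
    }
    verdicts <- annotate_truth(beats$times, beats$ventricular,
                               spec$duration_s, vf_interval = beats$vf_interval)
    if (spec$label == "TRUE_ALARM" && !verdicts[[spec$arrhythmia]])
      stop("contradictory spec: TRUE_ALARM ", spec$arrhythmia,
           " but the ground-truth definition is not met")
    if (spec$label == "FALSE_ALARM" && verdicts[[spec$arrhythmia]])
      stop("contradictory spec: FALSE_ALARM ", spec$arrhythmia,
           " but the ground-truth definition fires")
    id <- paste0(ALARM_TYPE_CODES[[spec$arrhythmia]],
                 sprintf("%05d", spec$seed %% 100000), "l")
    rec <- alarm_record(id, channels, arrhythmia = spec$arrhythmia,
                        alarm_time_s = spec$duration_s, label = spec$label)
    truth <- structure(list(beat_times = beats$times,
                            ventricular = beats$ventricular,
                            vf_interval = beats$vf_interval,
                            verdicts = verdicts),
                       class = "ground_truth")
    list(record = rec, truth = truth)
  })
}

#' Annotate ground truth per the standard arrhythmia definitions
#'
#' Applies the alarm definitions literally to a ground-truth beat train:
#' asystole — no QRS for at least 4 s; extreme bradycardia — heart rate
#' lower than 40 bpm for 5 consecutive beats; extreme tachycardia — heart
#' rate higher than 140 bpm for 17 consecutive beats; ventricular
#' tachycardia — 5 or more consecutive ventricular beats with heart rate
#' higher than 100 bpm; ventricular flutter/fibrillation — an oscillatory
#' waveform episode lasting at least 4 s (taken from `vf_interval`, a
#' waveform-level property, not from beat gaps).  The rate of an n-beat run
#' is `60 * (n - 1) / (t_n - t_1)`.  Boundary semantics: "at least" is
#' inclusive, "lower/higher than" strict (evaluated with a 1e-9 guard so
#' exact-boundary inputs are classified by the strict reading, not by
#' floating-point noise).
#'
#' @param beat_times Sorted numeric vector of true beat times, seconds.
#' @param ventricular Logical vector flagging ventricular beats.
#' @param duration_s Record duration; start/end count as gap edges for the
#'   asystole rule.
#' @param vf_interval `c(start, end)` of a fibrillatory episode, or `NULL`.
#' @return Named logical vector over the five alarm types.
#' @export
annotate_truth <- function(beat_times, ventricular = rep(FALSE, length(beat_times)),
                           duration_s = 300, vf_interval = NULL) {
  eps <- 1e-9
  t <- as.numeric(beat_times)
  stopifnot(!is.unsorted(t))
  gaps <- diff(c(0, t, duration_s))
  asystole <- any(gaps >= 4 - eps)
  run_rates <- function(times, k) {
    nb <- length(times)
    if (nb < k) return(numeric(0))
    i <- seq_len(nb - k + 1)
    60 * (k - 1) / (times[i + k - 1] - times[i])
  }
  brady <- any(run_rates(t, 5) < 40 - eps)
  tachy <- any(run_rates(t, 17) > 140 + eps)
  vtach <- FALSE
  if (any(ventricular)) {
    r <- rle(ventricular)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= 5)) {
      run_t <- t[starts[j]:ends[j]]
      nb <- length(run_t)
      if (60 * (nb - 1) / (run_t[nb] - run_t[1]) > 100 + eps) vtach <- TRUE
    }
  }
  vfib <- !is.null(vf_interval) && diff(vf_interval) >= 4 - eps
  c(ASYSTOLE = asystole, BRADYCARDIA = brady, TACHYCARDIA = tachy,
    VFIB = vfib, VTACH = vtach)
}

# ---------------------------------------------------------------------------
# Scenario library: the true/false mechanisms the classifier must separate.
# False alarms are driven by the artifact processes that plague real
# monitors: broadband bursts, flat lines, pacing spikes, tall T waves,
# and unreadable pulse channels next to a clean ECG.
# ---------------------------------------------------------------------------

#' Build the synth spec for one benchmark scenario
#'
#' @param arrhythmia Alarm type.
#' @param label `TRUE_ALARM` or `FALSE_ALARM`.
#' @param seed Scenario seed (also drives parameter draws).
#' @param pulse_channel `"PLETH"` or `"ABP"`.
#' @return A [synth_spec()].
#' @export
scenario_spec <- function(arrhythmia, label, seed, pulse_channel = "PLETH") {
  with_seed(derive_seed(seed, 17), {
    channels <- c("II", "V", pulse_channel)
    base <- stats::runif(1, 65, 90)
    ep <- NULL; nz <- list(); hr <- base
    variant <- seed %% 3
    if (label == "TRUE_ALARM") {
      ep <- switch(arrhythmia,
        ASYSTOLE    = list(gap_s = stats::runif(1, 4.3, 5.5),
                           gap_end_s = stats::runif(1, 298.5, 299.5)),
        BRADYCARDIA = list(rate_bpm = stats::runif(1, 30, 38),
                           n_beats = sample(5:8, 1)),
        TACHYCARDIA = list(rate_bpm = stats::runif(1, 148, 170),
                           n_beats = sample(18:26, 1)),
        VTACH       = list(rate_bpm = stats::runif(1, 110, 160),
                           n_beats = sample(5:12, 1)),
        VFIB        = list(onset_s = stats::runif(1, 291, 295.5),
                           freq_hz = stats::runif(1, 4, 7)))
      if (variant == 1) nz$wander_amp <- 0.15
    } else {
      # false alarms: the rhythm never satisfies the definition; an artifact
      # process supplies the mechanism that fooled the monitor
      if (arrhythmia == "TACHYCARDIA") hr <- stats::runif(1, 100, 125)
      if (arrhythmia == "BRADYCARDIA") hr <- stats::runif(1, 62, 80)
      burst <- function(channel = "II", dur = c(2, 4), amp = c(1.5, 3),
                        band = c(1, 40))
        list(at_s = stats::runif(1, 293, 297),
             dur_s = stats::runif(1, dur[1], dur[2]),
             amp = stats::runif(1, amp[1], amp[2]), band_hz = band,
             channel = channel)
      # slow asynchronous pacing: spikes sweep across the rhythm instead of
      # riding on the QRS complexes
      pacing <- list(pacing_rate_hz = stats::runif(1, 0.8, 1.0))
      nz <- switch(arrhythmia,
        # short bursts / brief flat lines: beats stay countable on ECG 1
        ASYSTOLE = switch(as.character(variant),
          "0" = list(bursts = list(burst(dur = c(1, 2)))),
          "1" = local({
            fstart <- stats::runif(1, 293, 294.5)
            list(flat_intervals = list(c(fstart, fstart + stats::runif(1, 2.2, 2.6))),
                 bursts = list(burst(dur = c(1, 1.5))))
          }),
          "2" = pacing),
        # the unreadable channel is the pulse channel (or the second lead):
        # the monitor's rate came from a noisy PPG next to a clean ECG
        BRADYCARDIA = switch(as.character(variant),
          "0" = list(ppg_noise_sd = stats::runif(1, 0.3, 0.6)),
          "1" = list(ppg_noise_sd = stats::runif(1, 0.3, 0.6),
                     bursts = list(burst(channel = "V"))),
          "2" = list(ppg_noise_sd = stats::runif(1, 0.4, 0.7),
                     wander_amp = stats::runif(1, 0.15, 0.3),
                     white_sd = stats::runif(1, 0.04, 0.08))),
        # rate never reaches threshold; brief bursts or pacing over-counting
        TACHYCARDIA = switch(as.character(variant),
          "0" = list(bursts = list(burst(dur = c(1, 1.5)))),
          "1" = list(wander_amp = stats::runif(1, 0.2, 0.35)),
          "2" = pacing),
        # broadband artifact, not an oscillatory rhythm
        VFIB = switch(as.character(variant),
          "0" = list(bursts = list(burst())),
          "1" = list(bursts = list(burst(band = c(1, 30))),
                     wander_amp = stats::runif(1, 0.15, 0.3)),
          "2" = c(pacing, list(bursts = list(burst(dur = c(1, 2)))))),
        # artifact mimicking wide complexes on lead 1, lead 2 clean
        VTACH = switch(as.character(variant),
          "0" = list(bursts = list(burst())),
          "1" = list(bursts = list(burst(band = c(2, 25))),
                     ppg_noise_sd = stats::runif(1, 0.2, 0.4)),
          "2" = c(pacing, list(bursts = list(burst(dur = c(1.5, 3)))))))
    }
    synth_spec(arrhythmia, label, seed = derive_seed(seed, 31),
               episode = ep, channels = channels, base_hr_bpm = hr,
               noise = nz)
  })
}

#' Generate a challenge-layout benchmark directory
#'
#' Writes `n_per_type_per_label` records for every alarm type and label
#' (10 scenarios per unit) in the WFDB layout plus an `answers.csv`
#' readable by [load_answers()].  Deterministic given `master_seed`.
#'
#' @param n_per_type_per_label Records per (arrhythmia, label) cell.
#' @param master_seed Integer master seed.
#' @param dir Output directory.
#' @return Invisibly, a data frame of record ids, types and labels.
#' @export
generate_benchmark <- function(n_per_type_per_label, master_seed, dir) {
  stopifnot(n_per_type_per_label >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  counter <- 0
  for (type in ARRHYTHMIA_TYPES) {
    for (label in c("TRUE_ALARM", "FALSE_ALARM")) {
      for (i in seq_len(n_per_type_per_label)) {
        counter <- counter + 1
        seed <- derive_seed(master_seed, counter * 101)
        spec <- scenario_spec(type, label, seed,
                              pulse_channel = if (counter %% 2) "PLETH" else "ABP")
        gen <- generate_record(spec)
        rec <- gen$record
        rec$record_id <- paste0(ALARM_TYPE_CODES[[type]],
                                sprintf("%04d", counter), "l")
        rec$label <- label
        write_alarm_record(rec, dir)
        rows[[counter]] <- data.frame(record_id = rec$record_id,
                                      arrhythmia = type, label = label)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_answers(stats::setNames(manifest$label, manifest$record_id),
                file.path(dir, "answers.csv"))
  invisible(manifest)
}
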