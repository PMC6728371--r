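#' @keywords internal
"_PACKAGE"

ARRHYTHMIA_TYPES <- c("ASYSTOLE", "BRADYCARDIA", "TACHYCARDIA", "VFIB", "VTACH")
ALARM_LABELS <- c("TRUE_ALARM", "FALSE_ALARM", "UNKNOWN")

# Record-id prefix -> alarm type, following the challenge naming convention.
ALARM_CODE_MAP <- c(a = "ASYSTOLE", b = "BRADYCARDIA", t = "TACHYCARDIA",
                    f = "VFIB", v = "VTACH")
ALARM_TYPE_CODES <- stats::setNames(names(ALARM_CODE_MAP), ALARM_CODE_MAP)

#' Classify a monitor channel from its signal name
#'
#' Deterministic mapping used when reading records: names containing
#' "PLETH" are photoplethysmogram channels, names containing "ABP" or "ART"
#' are arterial blood pressure channels, everything else is treated as an
#' ECG lead (II, V, aVR, MCL, ...).
#'
#' @param name Character vector of channel names.
#' @return Character vector with elements in `c("ECG", "PPG", "ABP")`.
#' @export
channel_kind <- function(name) {
  up <- toupper(name)
  kind <- rep("ECG", length(name))
  kind[grepl("PLETH", up)] <- "PPG"
  kind[grepl("ABP|ART", up)] <- "ABP"
  kind
}

#' Construct a monitor channel
#'
#' @param name Channel name as written in the record header (e.g. "II",
#'   "PLETH", "ABP").
#' @param samples Numeric vector of samples (a.u. for ECG/PPG, mmHg for ABP).
#' @param fs Sampling rate in Hz, > 0.
#' @param kind Channel kind; inferred from `name` by default.
#' @param mask Logical vector marking analyzable samples (same length as
#'   `samples`); defaults to all `TRUE`.
#' @return An object of class `icu_channel`.
#' @export
new_channel <- function(name, samples, fs, kind = channel_kind(name),
                        mask = NULL) {
  stopifnot(is.numeric(samples), length(fs) == 1, fs > 0)
  kind <- match.arg(kind, c("ECG", "PPG", "ABP"))
  if (is.null(mask)) mask <- rep(TRUE, length(samples))
  if (length(mask) != length(samples))
    stop("mask and samples must have equal length")
  structure(list(name = name, kind = kind, fs = fs,
                 samples = as.numeric(samples), mask = mask),
            class = "icu_channel")
}

#' Construct an alarm record
#'
#' One alarm event: the channels recorded by the bedside monitor up to the
#' alarm, the arrhythmia type the monitor announced, and (for training data)
#' the expert true/false annotation.  Channels are normalized so that ECG
#' leads come first.
#'
#' @param record_id Record identifier; its first character encodes the alarm
#'   type (a/b/t/f/v) in the challenge convention.
#' @param channels List of [new_channel()] objects; at least one ECG lead.
#' @param arrhythmia One of `ASYSTOLE`, `BRADYCARDIA`, `TACHYCARDIA`, `VFIB`,
#'   `VTACH`; decoded from `record_id` when omitted.
#' @param alarm_time_s Alarm time in seconds from record start (300 by
#'   convention).
#' @param label `TRUE_ALARM`, `FALSE_ALARM` or `UNKNOWN`.
#' @return An object of class `alarm_record`.
#' @export
alarm_record <- function(record_id, channels, arrhythmia = NULL,
                         alarm_time_s = 300, label = "UNKNOWN") {
  if (is.null(arrhythmia)) arrhythmia <- decode_alarm_type(record_id)
  arrhythmia <- match.arg(arrhythmia, ARRHYTHMIA_TYPES)
  label <- match.arg(label, ALARM_LABELS)
  if (!length(channels)) stop("record must contain at least one channel")
  kinds <- vapply(channels, function(ch) ch$kind, "")
  if (!any(kinds == "ECG")) stop("record must contain at least one ECG channel")
  fs <- vapply(channels, function(ch) ch$fs, 0)
  ns <- vapply(channels, function(ch) length(ch$samples), 0L)
  if (length(unique(fs)) != 1L || length(unique(ns)) != 1L)
    stop("all channels must share sampling rate and length")
  if (ns[1] / fs[1] < alarm_time_s)
    stop("record duration (", ns[1] / fs[1], " s) shorter than alarm time")
  # normalize: ECG channels first, preserving relative order
  ord <- order(kinds != "ECG")
  structure(list(record_id = record_id, arrhythmia = arrhythmia,
                 channels = channels[ord], alarm_time_s = alarm_time_s,
                 label = label, fs = fs[1], n_samples = ns[1]),
            class = "alarm_record")
}

decode_alarm_type <- function(record_id) {
  code <- substr(record_id, 1, 1)
  if (!code %in% names(ALARM_CODE_MAP))
    stop("cannot classify record id '", record_id,
         "': unknown alarm type code '", code, "'")
  unname(ALARM_CODE_MAP[code])
}

#' @export
print.alarm_record <- function(x, ...) {
  cat("<alarm_record> ", x$record_id, "  ", x$arrhythmia,
      "  label=", x$label, "\n", sep = "")
  cat("  fs=", x$fs, " Hz, ", x$n_samples, " samples (",
      round(x$n_samples / x$fs, 1), " s), alarm at ",
      x$alarm_time_s, " s\n", sep = "")
  for (ch in x$channels)
    cat("  - ", format(ch$name, width = 8), ch$kind, "\n", sep = " ")
  invisible(x)
}

#' Construct a beat series
#'
#' Fiducial points detected on one channel: R-peak times for ECG
#' (wavelet detector) or pulse-onset times for BP/PPG (double slope-sum
#' function).  Rejected beats (pacing spikes, T-wave over-sensing) stay in
#' the series with a reason code and are excluded from all rate features.
#'
#' @param times Numeric vector of fiducial times in seconds, strictly
#'   increasing.
#' @param amplitudes Signal value at each fiducial.
#' @param detector `"WAVELET_QRS"` or `"DOUBLE_SSF"`.
#' @param channel Name of the source channel.
#' @param rejected Character vector of rejection reasons
#'   (`"NONE"`, `"PACING_SPIKE"`, `"T_WAVE"`).
#' @param ventricular Logical vector flagging wide ventricular complexes.
#' @return Object of class `beat_series`.
#' @export
beat_series <- function(times, amplitudes = rep(NA_real_, length(times)),
                        detector = c("WAVELET_QRS", "DOUBLE_SSF"),
                        channel = NA_character_,
                        rejected = rep("NONE", length(times)),
                        ventricular = rep(FALSE, length(times))) {
  detector <- match.arg(detector)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("beat times must be strictly increasing")
  stopifnot(length(amplitudes) == length(times),
            length(rejected) == length(times),
            length(ventricular) == length(times))
  structure(list(times = times, amplitudes = as.numeric(amplitudes),
                 detector = detector, channel = channel,
                 rejected = rejected, ventricular = ventricular),
            class = "beat_series")
}

#' Accepted beats of a beat series
#'
#' @param beats A [beat_series()].
#' @return The series restricted to beats not rejected by the envelope rules.
#' @export
accepted_beats <- function(beats) {
  keep <- beats$rejected == "NONE"
  beat_series(beats$times[keep], beats$amplitudes[keep],
              detector = beats$detector, channel = beats$channel,
              rejected = beats$rejected[keep],
              ventricular = beats$ventricular[keep])
}

#' @export
print.beat_series <- function(x, ...) {
  cat("<beat_series> ", length(x$times), " beats (",
      sum(x$rejected != "NONE"), " rejected, ",
      sum(x$ventricular), " ventricular), detector=", x$detector,
      "\n", sep = "")
  invisible(x)
}

# restrict a beat series to a time window [start, end]
window_beats <- function(beats, window) {
  keep <- beats$times >= window[1] & beats$times <= window[2]
  beat_series(beats$times[keep], beats$amplitudes[keep],
              detector = beats$detector, channel = beats$channel,
              rejected = beats$rejected[keep],
              ventricular = beats$ventricular[keep])
}

# shift beat times by a constant (used when detection ran on a sub-segment)
shift_beats <- function(beats, offset_s) {
  beats$times <- beats$times + offset_s
  beats
}
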