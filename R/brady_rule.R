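#' Choose the most reliable channel of a record
#'
#' Bradycardia alarms are verified on the single most trustworthy waveform:
#' among channels with at least 3 accepted beats in the analysis window, the
#' one maximizing the template-correlation SQI wins; ties go to the first
#' channel in record order (ECG leads first).
#'
#' @param record An [alarm_record()].
#' @param beats Named list of [beat_series()] per channel name.
#' @param window `c(start, end)` analysis window in seconds.
#' @param cfg Configuration list.
#' @return The name of the chosen channel.  Errors when no channel
#'   qualifies (the caller treats that record as unclassifiable and defaults
#'   to a true alarm).
#' @export
most_reliable_channel <- function(record, beats, window,
                                  cfg = default_config()) {
  fs <- record$fs
  i0 <- round(window[1] * fs) + 1L
  i1 <- min(record$n_samples, round(window[2] * fs))
  best <- NULL; best_cor <- -Inf
  for (ch in record$channels) {
    b <- beats[[ch$name]]
    if (is.null(b)) next
    bw <- shift_beats(window_beats(b, window), -window[1])
    if (length(accepted_beats(bw)$times) < 3) next
    xw <- ch$samples[i0:i1]
    if (ch$kind == "ECG")
      xw <- remove_baseline(xw, fs, cfg$preprocess$baseline_order)
    co <- sqi_correlation(xw, fs, bw, cfg$features$template_half_window_s)
    if (is.finite(co) && co > best_cor) {   # strict: ties keep the earlier channel
      best_cor <- co; best <- ch$name
    }
  }
  if (is.null(best))
    stop("no channel with at least 3 beats in the window: record ",
         record$record_id, " is unclassifiable")
  best
}

#' Rule-based bradycardia alarm classification
#'
#' On the most reliable channel, the slowest rate over `run_beats`
#' consecutive beats in the window is computed
#' (`60 * (n - 1) / (t_n - t_1)`); the alarm is true iff that rate is
#' strictly slower than `threshold_bpm` (default 46 bpm).  Records with
#' fewer than `run_beats` beats on every channel — including completely
#' unreadable ones — are classified true: missing an extreme bradycardia is
#' heavily penalized, so the rule fails safe.  Measured rates are quantized
#' to the configured resolution (0.1 bpm) before the comparison so that
#' sub-millisecond detection jitter cannot flip a boundary-rate record.
#'
#' @param record An [alarm_record()].
#' @param beats Named list of [beat_series()] per channel name.
#' @param window Analysis window; defaults to the bradycardia window.
#' @param threshold_bpm Decision threshold, bpm.
#' @param run_beats Run length for the slowest-rate search.
#' @param cfg Configuration list.
#' @return `"TRUE_ALARM"` or `"FALSE_ALARM"`.
#' @export
classify_bradycardia <- function(record, beats,
                                 window = default_config()$features$windows$BRADYCARDIA,
                                 threshold_bpm = default_config()$brady$threshold_bpm,
                                 run_beats = default_config()$brady$run_beats,
                                 cfg = default_config()) {
  chan <- tryCatch(most_reliable_channel(record, beats, window, cfg),
                   error = function(e) NULL)
  if (is.null(chan)) return("TRUE_ALARM")    # fail-safe
  b <- accepted_beats(window_beats(beats[[chan]], window))
  t <- b$times
  if (length(t) < run_beats) return("TRUE_ALARM")
  i <- seq_len(length(t) - run_beats + 1)
  rates <- 60 * (run_beats - 1) / (t[i + run_beats - 1] - t[i])
  res <- cfg$features$rate_resolution_bpm
  slowest <- round(min(rates) / res) * res
  if (slowest < threshold_bpm) "TRUE_ALARM" else "FALSE_ALARM"
}
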