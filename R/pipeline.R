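#' Run preprocessing and beat detection on an alarm record
#'
#' Detection is performed on the final 30 s of the record (all analysis
#' windows lie inside it): per-channel flat-line masks are built; ECG leads
#' go through wavelet QRS detection, envelope estimation, pacing-spike /
#' T-wave rejection and ventricular flagging; BP and PPG channels go
#' through double-SSF pulse-onset detection, with the ABP abnormality
#' criteria extending the validity mask and removing abnormal beats.  Beats
#' inside masked spans are dropped.
#'
#' @param record An [alarm_record()].
#' @param cfg Configuration list.
#' @return List with `beats` (named [beat_series()] per channel, times in
#'   record coordinates), `masks` (validity masks over the full record),
#'   `env` (envelope sets per ECG channel, with attribute `offset_s`), and
#'   `segment_start_s`.
#' @export
process_record <- function(record, cfg = default_config()) {
  fs <- record$fs
  t0 <- max(0, record$alarm_time_s - 30)
  i0 <- round(t0 * fs) + 1L
  i1 <- min(record$n_samples, round(record$alarm_time_s * fs))
  masks <- build_validity_mask(record, cfg = cfg)
  beats <- list(); env <- list()
  for (ch in record$channels) {
    seg <- ch$samples[i0:i1]
    mseg <- masks[[ch$name]][i0:i1]
    if (ch$kind == "ECG") {
      b <- detect_qrs(seg, fs, cfg$detect, mask = mseg, channel = ch$name)
      e <- estimate_envelopes(seg, fs, cfg$detect$bands,
                              cfg$detect$envelope_smooth_s)
      b <- reject_false_peaks(b, e, cfg$detect)
      b <- flag_ventricular(b, e, fs, cfg$detect)
      attr(e, "offset_s") <- t0
      env[[ch$name]] <- e
    } else {
      b <- detect_pulse_onsets(seg, fs, cfg$detect, mask = mseg,
                               channel = ch$name)
      if (ch$kind == "ABP" && length(accepted_beats(b)$times)) {
        flags <- bp_abnormality(seg, fs, b, cfg$preprocess$bp)
        if (any(flags)) {
          keep <- !flags
          b <- beat_series(b$times[keep], b$amplitudes[keep],
                           detector = b$detector, channel = b$channel,
                           rejected = b$rejected[keep],
                           ventricular = b$ventricular[keep])
        }
      }
    }
    beats[[ch$name]] <- shift_beats(b, t0)
  }
  list(beats = beats, masks = masks, env = env, segment_start_s = t0)
}

#' Extract feature tables from a set of records
#'
#' Processes each record ([process_record()]) and assembles per-arrhythmia
#' feature tables via [extract_features()].
#'
#' @param records List of [alarm_record()] objects, or a directory of
#'   `.hea` files.
#' @param cfg Configuration list.
#' @param training Logical; enables true-VF window augmentation (requires
#'   labels on the records).
#' @param answers Optional named labels (used when `records` is a
#'   directory).
#' @return Named list of `feature_table`s by arrhythmia type.
#' @export
extract_feature_tables <- function(records, cfg = default_config(),
                                   training = FALSE, answers = NULL) {
  if (is.character(records)) {
    paths <- list.files(records, pattern = "\\.hea$", full.names = TRUE)
    records <- lapply(paths, read_alarm_record, answers = answers)
  }
  tabs <- list()
  for (rec in records) {
    pr <- process_record(rec, cfg)
    ft <- extract_features(rec, pr$beats, pr$masks, pr$env, cfg,
                           training = training)
    arr <- attr(ft, "arrhythmia")
    tabs[[arr]] <- if (is.null(tabs[[arr]])) ft
                   else bind_feature_tables(tabs[[arr]], ft)
  }
  tabs
}

#' Train the full per-arrhythmia model set
#'
#' Builds a cost-sensitive random-forest model ([build_final_model()]) for
#' every arrhythmia except bradycardia, which is classified by the
#' rule-based verifier ([classify_bradycardia()]) in the final
#' implementation.
#'
#' @param tables Named list of `feature_table`s from
#'   [extract_feature_tables()].
#' @param seed Master seed.
#' @param cfg Configuration list.
#' @return Named list of `trained_alarm_model`s.
#' @export
train_alarm_models <- function(tables, seed = 1, cfg = default_config()) {
  models <- list()
  for (arr in names(tables)) {
    if (arr == "BRADYCARDIA") next
    base_cfg <- rf_config(n_trees = cfg$model$n_trees,
                          cost_fp = cfg$model$cost_fp,
                          seed = derive_seed(seed, match(arr, ARRHYTHMIA_TYPES)))
    models[[arr]] <- build_final_model(tables[[arr]], base_cfg, cfg$model)
  }
  models
}

#' Classify one alarm record
#'
#' Dispatches bradycardia alarms to the rule-based verifier and all other
#' types to the trained random-forest model for that arrhythmia.
#'
#' @param record An [alarm_record()].
#' @param models Named list of `trained_alarm_model`s.
#' @param cfg Configuration list.
#' @return List with `label` and `method` (`"brady_rule"` or `"rf"`).
#' @export
classify_record <- function(record, models, cfg = default_config()) {
  pr <- process_record(record, cfg)
  if (record$arrhythmia == "BRADYCARDIA") {
    lab <- classify_bradycardia(record, pr$beats,
                                window = cfg$features$windows$BRADYCARDIA,
                                threshold_bpm = cfg$brady$threshold_bpm,
                                run_beats = cfg$brady$run_beats, cfg = cfg)
    return(list(label = lab, method = "brady_rule"))
  }
  model <- models[[record$arrhythmia]]
  if (is.null(model))
    stop("no trained model for arrhythmia ", record$arrhythmia)
  ft <- extract_features(record, pr$beats, pr$masks, pr$env, cfg,
                         training = FALSE)
  pred <- predict(model$forest,
                  as.data.frame(ft)[, model$forest$features, drop = FALSE])
  vote <- mean(pred$vote)
  list(label = if (vote >= 0.5) "TRUE_ALARM" else "FALSE_ALARM",
       method = "rf", vote = vote)
}

#' Classify a set of records
#'
#' @param records List of [alarm_record()]s or a directory of `.hea` files.
#' @param models Named list of `trained_alarm_model`s.
#' @param cfg Configuration list.
#' @return Data frame `record_id`, `arrhythmia`, `label`, `method`.
#' @export
classify_records <- function(records, models, cfg = default_config()) {
  if (is.character(records)) {
    paths <- list.files(records, pattern = "\\.hea$", full.names = TRUE)
    records <- lapply(paths, read_alarm_record)
  }
  rows <- lapply(records, function(rec) {
    r <- classify_record(rec, models, cfg)
    data.frame(record_id = rec$record_id, arrhythmia = rec$arrhythmia,
               label = r$label, method = r$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
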