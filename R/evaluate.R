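#' True-positive and true-negative rates
#'
#' `tp_rate = TP / (TP + FN)`; `tn_rate = TN / (TN + FP)`.  A zero
#' denominator yields `NA`.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return A proportion in `[0, 1]`, or `NA`.
#' @export
tp_rate <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' @rdname tp_rate
#' @export
tn_rate <- function(tn, fp) {
  if (tn < 0 || fp < 0) stop("counts must be non-negative")
  if (tn + fp == 0) return(NA_real_)
  tn / (tn + fp)
}

#' Challenge score
#'
#' `100 * (TP + TN) / (TP + TN + FP + 5 * FN)`: a missed true alarm (FN)
#' costs five times a surviving false alarm (FP), reflecting the clinical
#' asymmetry between a missed event and an unnecessary alert.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, not all zero.
#' @return Score in `[0, 100]`.
#' @export
challenge_score <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + tn + fp + fn == 0) stop("all-zero confusion counts")
  100 * (tp + tn) / (tp + tn + fp + 5 * fn)
}

#' Evaluate record-level predictions
#'
#' Compares predicted and true labels per record (records are counted once;
#' augmented feature rows must be collapsed before evaluation) and
#' assembles confusion counts, TP/TN rates and the challenge score, per
#' arrhythmia and pooled over all records jointly.
#'
#' @param truth Named character vector of true labels by record id.
#' @param predicted Named character vector of predicted labels.
#' @param arrhythmia Named character vector of alarm types by record id.
#' @return An `eval_report`: data frame with one row per arrhythmia plus a
#'   pooled row; columns `arrhythmia`, `tp`, `tn`, `fp`, `fn`, `tp_rate`,
#'   `tn_rate`, `score`.
#' @export
evaluate_predictions <- function(truth, predicted, arrhythmia) {
  if (!setequal(names(truth), names(predicted))) {
    only_t <- setdiff(names(truth), names(predicted))
    only_p <- setdiff(names(predicted), names(truth))
    stop("record sets differ; only in truth: ",
         paste(utils::head(only_t, 5), collapse = ", "),
         "; only in predictions: ",
         paste(utils::head(only_p, 5), collapse = ", "))
  }
  ids <- names(truth)
  predicted <- predicted[ids]
  arrhythmia <- arrhythmia[ids]
  one <- function(sel) {
    tp <- sum(truth[sel] == "TRUE_ALARM" & predicted[sel] == "TRUE_ALARM")
    tn <- sum(truth[sel] == "FALSE_ALARM" & predicted[sel] == "FALSE_ALARM")
    fp <- sum(truth[sel] == "FALSE_ALARM" & predicted[sel] == "TRUE_ALARM")
    fn <- sum(truth[sel] == "TRUE_ALARM" & predicted[sel] == "FALSE_ALARM")
    data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
               tp_rate = tp_rate(tp, fn), tn_rate = tn_rate(tn, fp),
               score = if (tp + tn + fp + fn > 0)
                 challenge_score(tp, tn, fp, fn) else NA_real_)
  }
  types <- intersect(ARRHYTHMIA_TYPES, unique(arrhythmia))
  rows <- lapply(types, function(a) cbind(arrhythmia = a, one(arrhythmia == a)))
  rows[[length(rows) + 1]] <- cbind(arrhythmia = "POOLED",
                                    one(rep(TRUE, length(ids))))
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(rep, class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$tp_rate <- sprintf("%5.1f", 100 * df$tp_rate)
  df$tn_rate <- sprintf("%5.1f", 100 * df$tn_rate)
  df$score <- sprintf("%6.2f", df$score)
  names(df) <- c("Arrhythmia", "TP", "TN", "FP", "FN", "TPR (%)", "TNR (%)",
                 "Score")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
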