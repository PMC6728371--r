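#' Random-forest configuration
#'
#' Settings for the cost-sensitive bagged-tree ensemble: 301 trees, the
#' square root of the feature count tried at each split, Gini splitting,
#' uniform class prior, false-positive cost fixed at 1 and a tunable
#' false-negative cost.  Costs enter as class weights multiplied with the
#' uniform prior — both during tree growing (via the split criterion) and at
#' the vote aggregation — so that with equal costs the ensemble degenerates
#' to a plain majority-vote forest.
#'
#' @param n_trees Number of trees.
#' @param cost_fp Cost of a false positive (kept at 1).
#' @param cost_fn Cost of a false negative, `>= cost_fp`.
#' @param seed Integer seed making training deterministic.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 301L, cost_fp = 1.0, cost_fn = 1.0, seed = 1L) {
  stopifnot(n_trees >= 1, cost_fp > 0, cost_fn >= cost_fp)
  structure(list(n_trees = as.integer(n_trees), cost_fp = cost_fp,
                 cost_fn = cost_fn, seed = as.integer(seed)),
            class = "rf_config")
}

CLASS_LEVELS <- c("FALSE_ALARM", "TRUE_ALARM")

# uniform prior (0.5/0.5) times the misclassification costs, normalized
class_weights <- function(cfg) {
  w <- c(FALSE_ALARM = 0.5 * cfg$cost_fp, TRUE_ALARM = 0.5 * cfg$cost_fn)
  w / sum(w)
}

.prep_training <- function(table, features = NULL) {
  X <- feature_matrix(table)
  if (!is.null(features)) {
    missing <- setdiff(features, names(X))
    if (length(missing))
      stop("features not in table: ", paste(missing, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  y <- factor(table$label, levels = CLASS_LEVELS)
  if (anyNA(y)) stop("labels must be TRUE_ALARM/FALSE_ALARM")
  if (length(unique(y)) < 2)
    stop("training table contains a single class: ", unique(as.character(y)))
  # median imputation on the training rows; all-missing columns fall back to 0
  med <- vapply(X, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.finite(m)) m else 0
  }, 0)
  for (j in seq_along(X)) X[[j]][!is.finite(X[[j]])] <- med[j]
  bad <- !vapply(X, function(col) all(is.finite(col)), TRUE)
  if (any(bad))
    stop("non-finite feature values after imputation: ",
         paste(names(X)[bad], collapse = ", "))
  list(X = X, y = y, medians = med)
}

#' Train a cost-sensitive random forest
#'
#' Bagged classification trees (Gini splits, `sqrt(p)` features per split)
#' grown on the median-imputed feature matrix with class weights
#' `class_weights(cfg)`.  Deterministic given `cfg$seed`.
#'
#' @param table A `feature_table` with known labels.
#' @param cfg An [rf_config()].
#' @param features Optional subset of feature names to train on.
#' @return An `alarm_forest` bundling the forest, the feature names, the
#'   imputation medians and the configuration.
#' @export
train_rf <- function(table, cfg = rf_config(), features = NULL) {
  prep <- .prep_training(table, features)
  w <- class_weights(cfg)
  rf <- with_seed(cfg$seed,
    randomForest::randomForest(prep$X, prep$y, ntree = cfg$n_trees,
                               mtry = max(1, floor(sqrt(ncol(prep$X)))),
                               classwt = w))
  structure(list(rf = rf, features = names(prep$X), medians = prep$medians,
                 classwt = w, cfg = cfg),
            class = "alarm_forest")
}

#' Predict alarm labels with a trained forest
#'
#' Missing values are imputed with the stored training medians; the per-tree
#' votes are aggregated under the cost/prior weighting, with ties resolved
#' to `TRUE_ALARM` (the fail-safe direction).
#'
#' @param object An `alarm_forest`.
#' @param newdata Data frame (or `feature_table`) whose feature columns must
#'   match the model's features exactly; unknown feature names are an error.
#' @param ... Unused.
#' @return Data frame with columns `label` and `vote` (weighted TRUE-alarm
#'   vote fraction in `[0, 1]`).
#' @export
predict.alarm_forest <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- feature_matrix(newdata)
  newdata <- as.data.frame(newdata)
  extra <- setdiff(names(newdata), c(object$features, META_COLUMNS))
  if (length(extra))
    stop("unknown feature names: ", paste(extra, collapse = ", "))
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("newdata lacks features: ", paste(missing, collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  for (j in seq_along(X))
    X[[j]][!is.finite(X[[j]])] <- object$medians[[names(X)[j]]]
  votes <- stats::predict(object$rf, X, type = "vote", norm.votes = TRUE)
  w <- object$classwt
  num <- votes[, "TRUE_ALARM"] * w["TRUE_ALARM"]
  den <- num + votes[, "FALSE_ALARM"] * w["FALSE_ALARM"]
  frac <- ifelse(den > 0, num / den, 0.5)
  data.frame(label = ifelse(frac >= 0.5, "TRUE_ALARM", "FALSE_ALARM"),
             vote = as.numeric(frac), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Out-of-bag permutation importance
#'
#' For each feature, the increase in out-of-bag prediction error when its
#' values are permuted across the out-of-bag observations, computed per
#' tree, averaged over the ensemble and divided by the standard deviation
#' over the ensemble.  A constant feature scores exactly 0 (permutation is
#' a no-op).
#'
#' @param table A `feature_table`.
#' @param cfg An [rf_config()].
#' @param features Optional feature subset.
#' @return Named numeric vector of importance scores.
#' @export
oob_importance <- function(table, cfg = rf_config(), features = NULL) {
  prep <- .prep_training(table, features)
  w <- class_weights(cfg)
  rf <- with_seed(cfg$seed,
    randomForest::randomForest(prep$X, prep$y, ntree = cfg$n_trees,
                               mtry = max(1, floor(sqrt(ncol(prep$X)))),
                               classwt = w, importance = TRUE))
  raw <- rf$importance[, "MeanDecreaseAccuracy"]
  sdv <- rf$importanceSD[, "MeanDecreaseAccuracy"]
  score <- ifelse(sdv > 0, raw / sdv, 0)
  stats::setNames(as.numeric(score), rownames(rf$importance))
}

# record-level aggregation of (possibly augmented) row predictions:
# mean weighted vote across the record's rows, ties fail-safe to TRUE
.collapse_to_records <- function(ids, votes) {
  agg <- tapply(votes, ids, mean)
  stats::setNames(ifelse(agg >= 0.5, "TRUE_ALARM", "FALSE_ALARM"), names(agg))
}

#' Leave-one-out cross-validated challenge score
#'
#' The cross-validation unit is the record: all rows sharing a `record_id`
#' (the augmented windows of a true VF alarm) are held out together, so
#' augmentation never leaks between training and test.  Held-out rows are
#' predicted, collapsed to one record-level label, and scored with the
#' challenge metric.
#'
#' @param table A `feature_table`.
#' @param cfg An [rf_config()].
#' @param features Optional feature subset.
#' @return List `score`, `tp`, `tn`, `fp`, `fn`, and `predictions` (named
#'   record-level labels).
#' @export
loocv_score <- function(table, cfg = rf_config(), features = NULL) {
  df <- as.data.frame(table)
  ids <- unique(df$record_id)
  if (length(ids) < 2) stop("need at least 2 records for cross-validation")
  votes <- numeric(0); vote_ids <- character(0)
  for (k in seq_along(ids)) {
    test <- df$record_id == ids[k]
    train_tab <- new_feature_table(df[!test, , drop = FALSE],
                                   attr(table, "arrhythmia"))
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, k)
    if (length(unique(train_tab$label)) < 2) {
      # degenerate fold (tiny tables): a one-class ensemble votes its class
      v <- as.numeric(train_tab$label[1] == "TRUE_ALARM")
      votes <- c(votes, rep(v, sum(test)))
    } else {
      fit <- train_rf(train_tab, fold_cfg, features)
      pr <- predict(fit, df[test, fit$features, drop = FALSE])
      votes <- c(votes, pr$vote)
    }
    vote_ids <- c(vote_ids, df$record_id[test])
  }
  pred <- .collapse_to_records(vote_ids, votes)
  truth <- stats::setNames(df$label[!duplicated(df$record_id)],
                           df$record_id[!duplicated(df$record_id)])
  truth <- truth[names(pred)]
  tp <- sum(truth == "TRUE_ALARM" & pred == "TRUE_ALARM")
  tn <- sum(truth == "FALSE_ALARM" & pred == "FALSE_ALARM")
  fp <- sum(truth == "FALSE_ALARM" & pred == "TRUE_ALARM")
  fn <- sum(truth == "TRUE_ALARM" & pred == "FALSE_ALARM")
  list(score = challenge_score(tp, tn, fp, fn), tp = tp, tn = tn, fp = fp,
       fn = fn, predictions = pred)
}

#' Forward feature selection with cross-validated score curves
#'
#' Features are ranked by their mean out-of-bag permutation importance
#' across the leave-one-record-out folds; classifiers are then built on the
#' top-1, top-2, ... feature subsets and scored by cross-validation.  The
#' whole procedure runs `repeats` times with distinct seeds; from the per-k
#' median score curve, `x` is the smallest subset size whose median score is
#' within `plateau_tol` of the best (the plateau point), and the final set
#' holds the top `ceiling(expand_factor * x)` features, then symmetrized so
#' that a feature selected on one ECG lead brings its twin on the other
#' lead.
#'
#' @param table A `feature_table`.
#' @param cfg An [rf_config()].
#' @param repeats Number of independent repetitions of ranking + curves.
#' @param plateau_tol Plateau tolerance in score units on the median curve.
#' @param max_k Cap on the curve length (subset sizes examined).
#' @param expand_factor Final-count expansion factor (1.2).
#' @return List: `ranking` (features by decreasing mean importance),
#'   `curve` (data frame k / mean_score / median_score), `x`,
#'   `final_features`, `importance` (mean scores).
#' @export
forward_selection <- function(table, cfg = rf_config(), repeats = 5,
                              plateau_tol = 0.5, max_k = NULL,
                              expand_factor = 1.2) {
  nms <- feature_names(table)
  if (length(nms) < 2) stop("need at least 2 features for selection")
  df <- as.data.frame(table)
  ids <- unique(df$record_id)
  K <- length(nms)
  if (!is.null(max_k)) K <- min(K, max_k)
  arr <- attr(table, "arrhythmia")
  imp_all <- NULL
  scores <- array(NA_real_, dim = c(repeats, K))
  for (r in seq_len(repeats)) {
    rep_cfg <- cfg
    rep_cfg$seed <- derive_seed(cfg$seed, 1000 + r)
    # importance across leave-one-record-out folds
    imp_mat <- vapply(seq_along(ids), function(k) {
      fold <- new_feature_table(df[df$record_id != ids[k], , drop = FALSE], arr)
      fcfg <- rep_cfg; fcfg$seed <- derive_seed(rep_cfg$seed, k)
      oob_importance(fold, fcfg)[nms]
    }, numeric(length(nms)))
    imp_r <- rowMeans(imp_mat)
    imp_all <- cbind(imp_all, imp_r)
    ranking_r <- nms[order(imp_r, decreasing = TRUE)]
    for (k in seq_len(K)) {
      kcfg <- rep_cfg; kcfg$seed <- derive_seed(rep_cfg$seed, 5000 + k)
      scores[r, k] <- loocv_score(table, kcfg, ranking_r[seq_len(k)])$score
    }
  }
  imp_mean <- rowMeans(imp_all)
  names(imp_mean) <- nms
  ranking <- nms[order(imp_mean, decreasing = TRUE)]
  med_curve <- apply(scores, 2, stats::median)
  mean_curve <- colMeans(scores)
  x <- which(med_curve >= max(med_curve) - plateau_tol)[1]
  n_final <- min(length(nms), ceiling(expand_factor * x))
  final <- ranking[seq_len(n_final)]
  final <- symmetrize_ecg_features(final, nms)
  list(ranking = ranking,
       curve = data.frame(k = seq_len(K), mean_score = mean_curve,
                          median_score = med_curve),
       x = x, final_features = final, importance = imp_mean)
}

# any ecg1_* feature brings its ecg2_* twin and vice versa (when available)
symmetrize_ecg_features <- function(selected, available) {
  twins <- character(0)
  for (f in selected) {
    if (startsWith(f, "ecg1_"))
      twins <- c(twins, sub("^ecg1_", "ecg2_", f))
    else if (startsWith(f, "ecg2_"))
      twins <- c(twins, sub("^ecg2_", "ecg1_", f))
  }
  union(selected, intersect(twins, available))
}

#' Grid search for the false-negative cost
#'
#' Evaluates the cross-validated challenge score over a grid of FN costs
#' (FP cost fixed at 1) and returns the maximizer; ties resolve to the
#' smallest cost.
#'
#' @param table A `feature_table`.
#' @param cfg An [rf_config()].
#' @param grid Candidate FN costs.
#' @param features Optional feature subset.
#' @return List `best_cost`, `best_score`, and the full `curve`
#'   (data frame cost_fn / score / tp / tn / fp / fn).
#' @export
tune_fn_cost <- function(table, cfg = rf_config(),
                         grid = default_config()$model$cost_fn_grid,
                         features = NULL) {
  if (!length(grid)) stop("empty cost grid")
  rows <- lapply(grid, function(cost) {
    ccfg <- cfg; ccfg$cost_fn <- cost
    r <- loocv_score(table, ccfg, features)
    data.frame(cost_fn = cost, score = r$score, tp = r$tp, tn = r$tn,
               fp = r$fp, fn = r$fn)
  })
  curve <- do.call(rbind, rows)
  best <- which(curve$score == max(curve$score))[1]   # smallest cost wins ties
  list(best_cost = curve$cost_fn[best], best_score = curve$score[best],
       curve = curve)
}

#' Build the final per-arrhythmia alarm classifier
#'
#' Runs forward feature selection, tunes the false-negative cost on the
#' selected features, and trains the final forest on all rows.  All
#' randomness derives from `cfg$seed`, so two runs with the same seed select
#' the same features and produce identical predictions.
#'
#' @param table A `feature_table` for one arrhythmia.
#' @param cfg An [rf_config()].
#' @param model_cfg Selection/tuning settings, `default_config()$model`.
#' @return A `trained_alarm_model`: the forest bundle plus selection
#'   diagnostics (importance, score curve, plateau point `x`, tuned cost
#'   curve).
#' @export
build_final_model <- function(table, cfg = rf_config(),
                              model_cfg = default_config()$model) {
  if (!nrow(table)) stop("empty feature table")
  arr <- attr(table, "arrhythmia")
  sel <- forward_selection(table, cfg, repeats = model_cfg$selection_repeats,
                           plateau_tol = model_cfg$plateau_tol,
                           max_k = model_cfg$max_k,
                           expand_factor = model_cfg$expand_factor)
  tune <- tune_fn_cost(table, cfg, model_cfg$cost_fn_grid, sel$final_features)
  final_cfg <- cfg
  final_cfg$cost_fn <- tune$best_cost
  forest <- train_rf(table, final_cfg, sel$final_features)
  structure(list(arrhythmia = arr, forest = forest,
                 selected_features = sel$final_features,
                 selection = sel, tuning = tune, cfg = final_cfg),
            class = "trained_alarm_model")
}

#' @export
print.trained_alarm_model <- function(x, ...) {
  cat("<trained_alarm_model> ", x$arrhythmia, "\n", sep = "")
  cat("  ", length(x$selected_features), " features (plateau x = ",
      x$selection$x, "), cost_fn = ", x$cfg$cost_fn,
      ", LOOCV score = ", round(x$tuning$best_score, 2), "\n", sep = "")
  invisible(x)
}

#' Save / load a trained alarm model bundle
#'
#' The bundle is a directory holding human-readable JSON metadata (selected
#' features, costs, seeds, score curves) next to the serialized forest.
#'
#' @param model A `trained_alarm_model`.
#' @param dir Bundle directory.
#' @return `read_model()` returns the model; `write_model()` the directory,
#'   invisibly.
#' @export
write_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(arrhythmia = model$arrhythmia,
               selected_features = model$selected_features,
               cost_fn = model$cfg$cost_fn, cost_fp = model$cfg$cost_fp,
               n_trees = model$cfg$n_trees, seed = model$cfg$seed,
               plateau_x = model$selection$x,
               score_curve = model$selection$curve,
               cost_curve = model$tuning$curve,
               medians = as.list(model$forest$medians))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
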