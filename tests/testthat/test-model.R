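test_that("training on a separable table reaches perfect training accuracy", {
  tab <- make_table(n = 100, p = 2, informative = 2, sep = 6)
  fit <- train_rf(tab, rf_config(n_trees = 101, seed = 1))
  pr <- predict(fit, tab)
  expect_equal(mean(pr$label == tab$label), 1.0)
  expect_true(all(pr$vote >= 0 & pr$vote <= 1))
})

test_that("degenerate tables and feature mismatches are rejected", {
  tab <- make_table(n = 20)
  one <- as.data.frame(tab)
  one$label <- "TRUE_ALARM"
  expect_error(train_rf(new_feature_table(one, "ASYSTOLE"),
                        rf_config()), "single class")
  fit <- train_rf(tab, rf_config(n_trees = 51, seed = 1))
  bad <- feature_matrix(tab)
  bad$bogus <- 1
  expect_error(predict(fit, bad), "unknown feature")
})

test_that("an all-missing vector falls back to the imputed prior class", {
  tab <- make_table(n = 60, p = 4, sep = 5)
  fit <- train_rf(tab, rf_config(n_trees = 101, seed = 2))
  empty <- as.data.frame(stats::setNames(as.list(rep(NA_real_, 4)),
                                         fit$features))
  p1 <- predict(fit, empty)
  p2 <- predict(fit, empty)
  expect_identical(p1$label, p2$label)
})

test_that("training is deterministic in the seed and stable across seeds", {
  tab <- make_table(n = 80, p = 6, sep = 5)
  f1 <- train_rf(tab, rf_config(n_trees = 101, seed = 5))
  f2 <- train_rf(tab, rf_config(n_trees = 101, seed = 5))
  expect_equal(predict(f1, tab)$vote, predict(f2, tab)$vote)
  f3 <- train_rf(tab, rf_config(n_trees = 101, seed = 6))
  expect_equal(predict(f3, tab)$label, predict(f1, tab)$label)
})

test_that("equal costs with uniform prior match a plain forest", {
  tab <- make_table(n = 80, p = 4, sep = 2)
  cfg <- rf_config(n_trees = 201, cost_fn = 1, cost_fp = 1, seed = 3)
  fit <- train_rf(tab, cfg)
  prep <- icualarms:::.prep_training(tab, NULL)
  plain <- icualarms:::with_seed(3,
    randomForest::randomForest(prep$X, prep$y, ntree = 201, mtry = 2))
  v1 <- predict(fit, tab)$vote
  v2 <- stats::predict(plain, prep$X, type = "vote")[, "TRUE_ALARM"]
  expect_lt(mean(abs(v1 - v2)), 0.05)
})

test_that("OOB permutation importance ranks the informative feature first", {
  withr::with_seed(7, {
    n <- 200
    y <- rep(c("TRUE_ALARM", "FALSE_ALARM"), each = n / 2)
    df <- data.frame(record_id = paste0("r", 1:n), window_start = 0, label = y,
                     A = as.numeric(y == "TRUE_ALARM") + rnorm(n, sd = 0.1))
    for (nm in c("B", "C", "D", "E", "F")) df[[nm]] <- rnorm(n)
    df$K <- 1   # constant
    tab <- new_feature_table(df, "VTACH")
    imp <- oob_importance(tab, rf_config(n_trees = 201, seed = 1))
    expect_equal(names(which.max(imp)), "A")
    expect_identical(unname(imp["K"]), 0)
    expect_lt(max(abs(imp[c("B", "C", "D", "E", "F")])), imp[["A"]] / 3)
  })
})

test_that("cross-validated score separates signal from shuffled labels", {
  tab <- make_table(n = 40, p = 4, sep = 6, seed = 11)
  cfg <- rf_config(n_trees = 101, seed = 4)
  expect_equal(loocv_score(tab, cfg)$score, 100)
  shuf <- as.data.frame(tab)
  shuf$label <- withr::with_seed(13, sample(shuf$label))
  s2 <- loocv_score(new_feature_table(shuf, "ASYSTOLE"), cfg)
  expect_lt(s2$score, 80)
  tiny <- as.data.frame(make_table(n = 2, p = 3, sep = 4))
  s3 <- loocv_score(new_feature_table(tiny, "ASYSTOLE"), cfg)
  expect_true(s3$score >= 0 && s3$score <= 100)
})

test_that("cross-validation keeps augmented rows of one record together", {
  tab <- make_table(n = 30, p = 3, sep = 5, seed = 21)
  df <- as.data.frame(tab)
  dup <- df[df$record_id == "r1", ][rep(1, 3), ]
  dup$window_start <- c(294, 295, 296)
  aug <- new_feature_table(rbind(df, dup), "ASYSTOLE")
  res <- loocv_score(aug, rf_config(n_trees = 51, seed = 2))
  expect_equal(length(res$predictions), 30)    # one prediction per record
  expect_equal(sum(res$tp, res$tn, res$fp, res$fn), 30)
})

test_that("forward selection finds the informative features and the 1.2 rule", {
  tab <- make_table(n = 50, p = 10, informative = 2, sep = 4, seed = 31)
  sel <- forward_selection(tab, rf_config(n_trees = 101, seed = 5),
                           repeats = 2, max_k = 6)
  expect_lte(sel$x, 4)
  expect_true(all(c("f1", "f2") %in% sel$final_features))
  expect_gte(length(sel$final_features), ceiling(1.2 * sel$x))
  expect_equal(ceiling(1.2 * 5), 6)   # the expansion arithmetic at x = 5
})

test_that("selected ECG features are symmetrized across the two leads", {
  nms <- c("ecg1_sqi_correlation", "ecg2_sqi_correlation",
           "ecg1_max_rr", "ecg2_max_rr", "ppg_max_rr")
  out <- icualarms:::symmetrize_ecg_features(
    c("ecg1_sqi_correlation", "ecg2_max_rr", "ppg_max_rr"), nms)
  expect_true(all(c("ecg2_sqi_correlation", "ecg1_max_rr") %in% out))
  tab <- make_table(n = 40, p = 5, informative = 2, sep = 4, seed = 41,
                    names_ = nms)
  sel <- forward_selection(tab, rf_config(n_trees = 101, seed = 6),
                           repeats = 2, max_k = 4)
  for (f in grep("^ecg1_", sel$final_features, value = TRUE))
    expect_true(sub("^ecg1_", "ecg2_", f) %in% sel$final_features)
  for (f in grep("^ecg2_", sel$final_features, value = TRUE))
    expect_true(sub("^ecg2_", "ecg1_", f) %in% sel$final_features)
})

test_that("cost tuning returns the smallest maximizing cost", {
  tab <- make_table(n = 30, p = 3, sep = 6, seed = 51)
  cfg <- rf_config(n_trees = 51, seed = 7)
  one <- tune_fn_cost(tab, cfg, grid = 1.3)
  expect_equal(one$best_cost, 1.3)
  # separable table scores 100 at every cost: tie resolves to the smallest
  tie <- tune_fn_cost(tab, cfg, grid = c(1.0, 1.2, 1.4))
  expect_equal(tie$best_cost, 1.0)
  expect_error(tune_fn_cost(tab, cfg, grid = numeric(0)), "empty")
})

test_that("the final model builder is deterministic and complete", {
  tab <- make_table(n = 40, p = 6, informative = 2, sep = 4, seed = 61)
  cfg <- rf_config(n_trees = 101, seed = 8)
  mcfg <- default_config()$model
  mcfg$selection_repeats <- 2; mcfg$max_k <- 4; mcfg$cost_fn_grid <- c(1, 1.2)
  m1 <- build_final_model(tab, cfg, mcfg)
  m2 <- build_final_model(tab, cfg, mcfg)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_identical(m1$cfg$cost_fn, m2$cfg$cost_fn)
  expect_true(all(c("f1", "f2") %in% m1$selected_features))
  expect_error(build_final_model(tab[0, ], cfg, mcfg), "empty")
  dir <- withr::local_tempdir()
  write_model(m1, dir)
  back <- read_model(dir)
  expect_identical(back$selected_features, m1$selected_features)
  expect_true(file.exists(file.path(dir, "model.json")))
})
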