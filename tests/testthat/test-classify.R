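test_that("grouped stratified folds partition participants and balance AF", {
  ids <- sprintf("P%02d", 1:67)
  labels <- c(rep("AF", 23), rep("NON_AF", 44))
  folds <- make_group_stratified_folds(ids, labels, k = 5, seed = 3)

  expect_setequal(folds$participant_id, ids)
  expect_identical(anyDuplicated(folds$participant_id), 0L)
  sizes <- table(folds$fold)
  expect_true(all(sizes %in% 13:14))
  af_per_fold <- table(folds$fold[folds$label == "AF"])
  expect_true(all(af_per_fold %in% 4:5))

  f1 <- make_group_stratified_folds(ids, labels, k = 1, seed = 3)
  expect_true(all(f1$fold == 1))
  expect_error(make_group_stratified_folds(ids, labels, k = 100), "k must")
  expect_error(make_group_stratified_folds(c("a", "a"), c("AF", "AF"), 1),
               "unique")
})

test_that("all four classifier families fit, score, and separate toy data", {
  toy <- toy_features()
  configs <- list(
    classifier_config("DT", spectrum_setting(0, 10, 2), max_depth = 3),
    classifier_config("RF", spectrum_setting(0, 10, 2), max_depth = 5),
    classifier_config("LR", spectrum_setting(0, 10, 2), C = 1),
    classifier_config("ADA", spectrum_setting(0, 10, 2), max_depth = 7,
                      learning_rate = 0.9))
  for (cfg in configs) {
    pred <- fit_predict(toy$x, toy$y, toy$x, cfg, seed = 5)
    expect_gte(mean(pred$predicted == toy$y), 0.95)
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    # determinism
    pred2 <- fit_predict(toy$x, toy$y, toy$x, cfg, seed = 5)
    expect_identical(pred$score, pred2$score)
  }

  # single-class training degenerates to a constant prediction
  one <- fit_predict(toy$x[1:5, ], rep("AF", 5), toy$x[1:3, ],
                     configs[[1]], seed = 1)
  expect_true(all(one$predicted == "AF"))
  expect_true(all(one$score == 1))

  m <- fit_classifier(toy$x, toy$y, configs[[2]], seed = 1)
  expect_error(predict_af_score(m, toy$x[, 1, drop = FALSE]), "mismatch")

  expect_error(classifier_config("ADA", spectrum_setting(0, 10, 3),
                                 max_depth = 7), "learning_rate")
})

test_that("grid search prefers informative features and never leaks subjects", {
  # features from harmonic-band power separate; white-noise power does not
  withr::with_seed(55, {
    n_part <- 12
    meta_rows <- list()
    power <- list()
    for (i in seq_len(n_part)) {
      lab <- if (i <= 5) "AF" else "NON_AF"
      for (bl in 1:6) {
        sig <- if (lab == "NON_AF") c(5, 4, 3) else c(1, 1, 1)
        low <- abs(rnorm(3, sig, 0.3))      # informative band (0-10 Hz)
        high <- rexp(3)                     # uninformative band (>100 Hz)
        power[[length(power) + 1]] <- c(low, high)
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          participant_id = sprintf("S%02d", i), placement = "BCG2",
          start_sample = (bl - 1) * 2048, label = lab,
          raw_max = 33000, std_max = 3, included = TRUE,
          spec_row = length(power), stringsAsFactors = FALSE)
      }
    }
    spectra <- list(meta = do.call(rbind, meta_rows),
                    power = do.call(rbind, power),
                    freq = c(1, 4, 8, 110, 150, 250))
  })
  cfg_info <- classifier_config("DT", spectrum_setting(0, 10, 3),
                                max_depth = 3)
  cfg_noise <- classifier_config("DT", spectrum_setting(100, 250, 3),
                                 max_depth = 3)

  single <- grid_search(spectra, list(cfg_noise), k = 3, seed = 9)
  expect_identical(single$best_index, 1L)
  expect_identical(length(single$best_cv$fold_accuracies), 3L)

  gs <- grid_search(spectra, list(cfg_noise, cfg_info), k = 3, seed = 9)
  expect_identical(gs$best_index, 2L)
  expect_gt(gs$cv$mean_accuracy[2], gs$cv$mean_accuracy[1])

  # leakage audit: folds are a partition, so train/validation participant
  # sets are disjoint for every fold
  for (f in unique(gs$folds$fold)) {
    val <- gs$folds$participant_id[gs$folds$fold == f]
    train <- gs$folds$participant_id[gs$folds$fold != f]
    expect_length(intersect(val, train), 0)
  }

  expect_error(grid_search(spectra, list()), "empty grid")
})

test_that("leave-one-participant-out accuracies match a hand trace", {
  # constant features: every fit predicts the majority training label
  meta <- data.frame(
    participant_id = c(rep("A", 3), rep("B", 5)), placement = "BCG2",
    start_sample = 0:7 * 2048,
    label = c(rep("AF", 3), rep("NON_AF", 5)),
    raw_max = 33000, std_max = 3, included = TRUE, spec_row = 1:8,
    stringsAsFactors = FALSE)
  spectra <- list(meta = meta,
                  power = matrix(1, 8, 3), freq = c(1, 2, 3))
  cfg <- classifier_config("DT", spectrum_setting(0, 3, 3), max_depth = 1)
  res <- loocv_by_participant(spectra, cfg, seed = 1)
  # leaving A out trains on all-NON_AF -> constant NON_AF -> A scores 0;
  # leaving B out trains on all-AF -> constant AF -> B scores 0
  expect_identical(res$per_participant$accuracy, c(0, 0))
  expect_identical(res$mean, 0)

  # ceiling case: separable features, two participants per class so every
  # leave-one-out training set still contains both classes
  meta2 <- data.frame(
    participant_id = rep(c("A", "B", "C", "D"), each = 3),
    placement = "BCG2", start_sample = rep(0:2 * 2048, 4),
    label = rep(c("AF", "AF", "NON_AF", "NON_AF"), each = 3),
    raw_max = 33000, std_max = 3, included = TRUE, spec_row = 1:12,
    stringsAsFactors = FALSE)
  sep <- list(meta = meta2,
              power = rbind(matrix(9, 6, 3), matrix(1, 6, 3)) +
                withr::with_seed(2, matrix(rnorm(36, 0, 0.01), 12, 3)),
              freq = c(1, 2, 3))
  res2 <- loocv_by_participant(sep, cfg, seed = 1)
  expect_identical(res2$mean, 1)
  expect_identical(res2$sd, 0)
  expect_identical(nrow(res2$per_participant), 4L)

  expect_error(loocv_by_participant(
    list(meta = meta[meta$participant_id == "A", ],
         power = spectra$power, freq = spectra$freq), cfg), "participants")
})

test_that("confusion metrics obey their identities on random matrices", {
  withr::with_seed(123, {
    for (i in 1:1000) {
      cm <- rmultinom(1, sample(4:200, 1), prob = runif(4, 0.05, 1))[, 1]
      tp <- cm[1]; fp <- cm[2]; tn <- cm[3]; fn <- cm[4]
      truth <- c(rep("AF", tp + fn), rep("NON_AF", fp + tn))
      predicted <- c(rep("AF", tp), rep("NON_AF", fn),
                     rep("AF", fp), rep("NON_AF", tn))
      r <- suppressWarnings(evaluate(predicted, truth))
      expect_equal(r$accuracy, (tp + tn) / sum(cm))
      if (tp + fn > 0) expect_equal(r$recall, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(r$specificity, tn / (tn + fp))
      if (tp + fp > 0) expect_equal(r$precision, tp / (tp + fp))
      if (tp + fn > 0 && tp + fp > 0 && tp > 0)
        expect_equal(r$f1,
                     2 * r$recall * r$precision / (r$recall + r$precision))
    }
  })

  expect_warning(evaluate(rep("NON_AF", 4), rep("NON_AF", 4)), "recall")
  all_good <- evaluate(c("AF", "NON_AF"), c("AF", "NON_AF"), c(0.9, 0.1))
  expect_identical(all_good$accuracy, 1)
  expect_identical(all_good$auc, 1)
  expect_error(evaluate(character(0), character(0)), "no predictions")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  withr::with_seed(31, {
    for (i in 1:30) {
      n1 <- sample(3:40, 1); n0 <- sample(3:40, 1)
      truth <- c(rep("AF", n1), rep("NON_AF", n0))
      score <- c(rnorm(n1, 0.5), rnorm(n0))
      if (i %% 3 == 0) score <- round(score, 1)   # force ties
      r <- evaluate(ifelse(score >= 0.5, "AF", "NON_AF"), truth, score)
      u <- unname(wilcox.test(score[truth == "AF"],
                              score[truth == "NON_AF"],
                              exact = FALSE)$statistic)
      expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
      if (requireNamespace("pROC", quietly = TRUE)) {
        expect_equal(r$auc,
                     as.numeric(pROC::auc(pROC::roc(
                       truth, score, levels = c("NON_AF", "AF"),
                       direction = "<", quiet = TRUE))),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("reporting rounds half away from zero to two decimals", {
  r <- structure(list(accuracy = 0.875, recall = 0.72, specificity = 0.965,
                      precision = 0.92, f1 = 0.805, auc = 0.885),
                 class = "eval_report")
  out <- format_report(r)
  expect_identical(unname(out),
                   c(0.88, 0.72, 0.97, 0.92, 0.81, 0.89))
})

test_that("cross-location application is self-consistent and complete", {
  p <- tiny_params(artifact_rate_per_min = 0, noise_sd = 10)
  co <- generate_cohort(3, 3, p, seed = 41)
  tr <- cohort_spectra(co, "BCG2")
  te <- cohort_spectra(generate_cohort(2, 2, p, seed = 42),
                       c("BCG1", "BCG2"))
  cfg <- classifier_config("RF", spectrum_setting(0, 10, 30), max_depth = 5)
  model <- train_model(tr, cfg, seed = 7)

  grid_rep <- cross_location_apply(model, te, c("BCG1", "BCG2"))
  expect_identical(nrow(grid_rep), 2L)
  expect_true(all(c("accuracy", "recall", "specificity", "precision",
                    "f1", "auc") %in% names(grid_rep)))

  # self-application equals a direct evaluation on the same placement
  own <- te
  own$meta <- own$meta[own$meta$placement == "BCG2", ]
  preds <- apply_model(model, own)
  direct <- evaluate(preds$predicted, preds$label, preds$score)
  expect_equal(grid_rep$accuracy[grid_rep$placement == "BCG2"],
               direct$accuracy)
  expect_equal(grid_rep$auc[grid_rep$placement == "BCG2"], direct$auc)
})
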