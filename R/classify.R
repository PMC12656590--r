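#' Define a classifier configuration
#'
#' A configuration pairs a classifier family with its tuned hyperparameters
#' and the spectral featurization setting it is trained on — the unit of the
#' grid search. Families and their tuned hyperparameters: `DT` (decision
#' tree, `max_depth`), `RF` (random forest, `max_depth`), `LR` (L2-penalized
#' logistic regression, `C`), `ADA` (AdaBoost over depth-limited decision
#' trees, `max_depth` + `learning_rate`).
#'
#' @param family One of `"DT"`, `"RF"`, `"LR"`, `"ADA"`.
#' @param setting A [spectrum_setting()].
#' @param max_depth Tree depth (DT/RF/ADA).
#' @param C Inverse regularization strength (LR).
#' @param learning_rate Boosting shrinkage (ADA).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(family, setting, max_depth = NULL, C = NULL,
                              learning_rate = NULL) {
  family <- match.arg(family, c("DT", "RF", "LR", "ADA"))
  if (family %in% c("DT", "RF", "ADA") && is.null(max_depth))
    stop_param(family, " requires max_depth")
  if (family == "LR" && is.null(C)) stop_param("LR requires C")
  if (family == "ADA" && is.null(learning_rate))
    stop_param("ADA requires learning_rate")
  structure(list(family = family, setting = setting, max_depth = max_depth,
                 C = C, learning_rate = learning_rate),
            class = "classifier_config")
}

#' The full hyperparameter/featurization tuning grid
#'
#' Enumerates every combination of low cutoff (0, 0.5, 0.7, 1.0, 1.2 Hz),
#' high cutoff (10, 20, 40, 250 Hz), number of bins (3, 5, 10, 30, 40, 50,
#' 100, 150) and family-specific hyperparameters (DT/RF max_depth grids, the
#' LR C ladder 1e-8..1e8, ADA max_depth 1-8 x learning_rate 1.0/0.9/0.8), in
#' deterministic order (family, then hyperparameters, then setting), which is
#' also the grid-search tie-break order.
#'
#' @param families Families to include.
#' @param lowcuts,highcuts,nbins Featurization sub-grids (Hz / Hz / count).
#' @return List of [classifier_config()] objects.
#' @export
default_grid <- function(families = c("DT", "RF", "LR", "ADA"),
                         lowcuts = c(0, 0.5, 0.7, 1.0, 1.2),
                         highcuts = c(10, 20, 40, 250),
                         nbins = c(3, 5, 10, 30, 40, 50, 100, 150)) {
  settings <- list()
  for (lc in lowcuts) for (hc in highcuts) for (nb in nbins)
    settings[[length(settings) + 1]] <- spectrum_setting(lc, hc, nb)
  grid <- list()
  add <- function(cfg) grid[[length(grid) + 1]] <<- cfg
  for (fam in families) {
    if (fam == "DT")
      for (md in c(1, 3, 5, 7, 10, 15)) for (s in settings)
        add(classifier_config("DT", s, max_depth = md))
    if (fam == "RF")
      for (md in c(1, 3, 5, 7, 10, 15, 20, 25, 30, 40)) for (s in settings)
        add(classifier_config("RF", s, max_depth = md))
    if (fam == "LR")
      for (C in 10^seq(-8, 8, by = 2)) for (s in settings)
        add(classifier_config("LR", s, C = C))
    if (fam == "ADA")
      for (lr in c(1.0, 0.9, 0.8)) for (md in 1:8) for (s in settings)
        add(classifier_config("ADA", s, max_depth = md,
                              learning_rate = lr))
  }
  grid
}

rhythm_factor <- function(y) factor(y, levels = c("NON_AF", "AF"))

rpart_ctrl <- function(max_depth) {
  rpart::rpart.control(maxdepth = min(max_depth, 30), cp = 0, minsplit = 2,
                       minbucket = 1, xval = 0)
}

# AdaBoost (SAMME) over depth-limited CART trees with learning-rate
# shrinkage. Score is the alpha-weighted vote share for AF in [0, 1].
fit_adaboost <- function(x, y, max_depth, learning_rate,
                         n_estimators = 50) {
  df <- as.data.frame(x)
  df$.y <- rhythm_factor(y)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                        method = "class", control = rpart_ctrl(max_depth))
    pred <- predict(fit, df, type = "class")
    mis <- as.numeric(pred != df$.y)
    err <- sum(w * mis)
    if (err <= 1e-12) {            # perfect learner dominates the ensemble
      trees[[m]] <- fit
      alphas[m] <- learning_rate * log(1e12)
      break
    }
    if (err >= 0.5) {              # no better than chance: stop boosting
      if (m == 1) {
        trees[[1]] <- fit
        alphas[1] <- 1e-10
      }
      break
    }
    a <- learning_rate * log((1 - err) / err)
    trees[[m]] <- fit
    alphas[m] <- a
    w <- w * exp(a * mis)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas), class = "bcg_adaboost")
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  votes <- numeric(nrow(df))
  for (m in seq_along(model$trees)) {
    pred <- predict(model$trees[[m]], df, type = "class")
    votes <- votes + model$alphas[m] * as.numeric(pred == "AF")
  }
  votes / sum(model$alphas)
}

#' Fit a classifier under one configuration
#'
#' Dispatches on the family: CART (`rpart`, depth-limited, unpruned), random
#' forest (`randomForest`, 100 trees, depth mapped to `maxnodes = 2^depth`),
#' L2 logistic regression (`glmnet`, ridge with `lambda = 1/(C*n)` so the `C`
#' grid has its usual inverse-regularization meaning), or the in-package
#' AdaBoost. A single-class training set yields a constant model.
#'
#' @param x Feature matrix.
#' @param y Labels (`"AF"`/`"NON_AF"`).
#' @param config A [classifier_config()].
#' @param seed Integer seed (random forest bootstrap).
#' @return Model object of class `bcg_model`.
#' @export
fit_classifier <- function(x, y, config, seed = 1L) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop_param("x/y length mismatch")
  classes <- unique(y)
  if (length(classes) < 2) {
    fit <- list(constant = classes)
    return(structure(list(fit = fit, config = config, constant = classes,
                          n_features = ncol(x)), class = "bcg_model"))
  }
  yf <- rhythm_factor(y)
  fit <- with_seed(seed, switch(
    config$family,
    DT = {
      df <- as.data.frame(x)
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart_ctrl(config$max_depth))
    },
    RF = randomForest::randomForest(
      x, yf, ntree = 100,
      maxnodes = min(2^min(config$max_depth, 30), nrow(x))),
    LR = {
      xx <- if (ncol(x) == 1) cbind(x, .pad = 0) else x
      glmnet::glmnet(xx, yf, family = "binomial", alpha = 0,
                     lambda = 1 / (config$C * nrow(xx)),
                     standardize = FALSE)
    },
    ADA = fit_adaboost(x, y, config$max_depth, config$learning_rate)
  ))
  structure(list(fit = fit, config = config, constant = NULL,
                 n_features = ncol(x)), class = "bcg_model")
}

#' AF-class score of a fitted model
#'
#' @param model A `bcg_model` from [fit_classifier()].
#' @param x Feature matrix under the model's featurization setting.
#' @return Numeric vector in `[0, 1]`; higher means more AF-like.
#' @export
predict_af_score <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop_param("feature length mismatch: model expects ", model$n_features)
  if (!is.null(model$constant))
    return(rep(if (model$constant == "AF") 1 else 0, nrow(x)))
  switch(
    model$config$family,
    DT = predict(model$fit, as.data.frame(x), type = "prob")[, "AF"],
    RF = predict(model$fit, x, type = "prob")[, "AF"],
    LR = {
      xx <- if (ncol(x) == 1) cbind(x, .pad = 0) else x
      as.numeric(predict(model$fit, xx, type = "response"))
    },
    ADA = predict_adaboost(model$fit, x)
  )
}

#' Fit on a training set and score a test set
#'
#' @param train_x,train_y Training features and labels.
#' @param test_x Test features (same featurization setting).
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return data.frame with `predicted` (AF iff score >= 0.5) and `score`.
#' @export
fit_predict <- function(train_x, train_y, test_x, config, seed = 1L) {
  model <- fit_classifier(train_x, train_y, config, seed)
  score <- predict_af_score(model, test_x)
  data.frame(predicted = ifelse(score >= 0.5, "AF", "NON_AF"),
             score = score, stringsAsFactors = FALSE)
}

#' Participant-grouped stratified fold assignment
#'
#' Partitions participants (never blocks) into `k` folds while keeping the AF
#' prevalence of every fold within one participant of the global prevalence:
#' AF participants are shuffled and dealt round-robin across folds, then
#' non-AF participants are dealt greedily onto the currently smallest folds.
#' All blocks of a participant inherit its fold, which is what prevents
#' within-subject leakage between training and validation.
#'
#' @param ids Participant ids.
#' @param labels Participant labels aligned with `ids`.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffles.
#' @return data.frame with `participant_id`, `label`, `fold`.
#' @export
make_group_stratified_folds <- function(ids, labels, k, seed = 1L) {
  if (anyDuplicated(ids)) stop_param("participant ids must be unique")
  if (k < 1 || k > length(ids)) stop_param("k must be in [1, #participants]")
  with_seed(seed, {
    fold <- integer(length(ids))
    names(fold) <- ids
    sizes <- integer(k)
    for (lab in c("AF", "NON_AF")) {
      members <- sample(ids[labels == lab])
      for (i in seq_along(members)) {
        f <- order(sizes)[1]          # smallest fold first; stable ties
        fold[members[i]] <- f
        sizes[f] <- sizes[f] + 1
      }
    }
    data.frame(participant_id = ids, label = labels,
               fold = unname(fold[ids]), stringsAsFactors = FALSE)
  })
}

participant_table <- function(meta) {
  u <- unique(meta[, c("participant_id", "label")])
  rownames(u) <- NULL
  u
}

#' Grid search with stratified group five-fold cross-validation
#'
#' Evaluates every configuration by refitting per fold on the fold-specific
#' featurization of the included blocks: validation-fold participants are
#' held out entirely, the model is trained on the remaining participants'
#' blocks, and the fold accuracy is the block-level accuracy on the held-out
#' participants. The winner maximizes mean fold accuracy; ties break toward
#' the earliest configuration in grid order.
#'
#' @param spectra A [cohort_spectra()] object (training cohort).
#' @param grid List of [classifier_config()]s.
#' @param k Number of folds.
#' @param seed Integer seed (folds + model fits).
#' @return List with `best` (config), `best_index`, `best_cv` (mean/sd/fold
#'   accuracies of the winner) and `cv` (data.frame over the whole grid).
#' @export
grid_search <- function(spectra, grid, k = 5, seed = 1L) {
  if (!length(grid)) stop_param("empty grid")
  inc_meta <- spectra$meta[spectra$meta$included, , drop = FALSE]
  if (!nrow(inc_meta)) stop_param("no included blocks after noise exclusion")
  pt <- participant_table(inc_meta)
  folds <- make_group_stratified_folds(pt$participant_id, pt$label, k, seed)

  setting_key <- function(s) paste(s$lowcut_hz, s$highcut_hz, s$nbins)
  feat_cache <- new.env(parent = emptyenv())
  results <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    cfg <- grid[[g]]
    key <- setting_key(cfg$setting)
    if (!exists(key, envir = feat_cache, inherits = FALSE))
      assign(key, bin_features(spectra, cfg$setting), envir = feat_cache)
    feats <- feat_cache[[key]]
    fold_of <- folds$fold[match(feats$meta$participant_id,
                                folds$participant_id)]
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold_of != f
      te <- fold_of == f
      if (!any(te)) return(NA_real_)
      pred <- fit_predict(feats$x[tr, , drop = FALSE],
                          feats$meta$label[tr],
                          feats$x[te, , drop = FALSE], cfg,
                          seed = derive_seed(seed, g, f))
      mean(pred$predicted == feats$meta$label[te])
    }, numeric(1))
    results[[g]] <- list(fold_accuracies = acc,
                         mean_accuracy = mean(acc, na.rm = TRUE),
                         sd_accuracy = stats::sd(acc[!is.na(acc)]))
  }
  means <- vapply(results, `[[`, numeric(1), "mean_accuracy")
  best <- which.max(means)   # first maximum = earliest in grid order
  cv <- data.frame(
    index = seq_along(grid),
    family = vapply(grid, `[[`, character(1), "family"),
    lowcut = vapply(grid, function(g) g$setting$lowcut_hz, numeric(1)),
    highcut = vapply(grid, function(g) g$setting$highcut_hz, numeric(1)),
    nbins = vapply(grid, function(g) g$setting$nbins, numeric(1)),
    mean_accuracy = means,
    sd_accuracy = vapply(results, `[[`, numeric(1), "sd_accuracy")
  )
  list(best = grid[[best]], best_index = best, best_cv = results[[best]],
       cv = cv, folds = folds)
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per participant: the model is refit without that participant and
#' the participant's accuracy is the fraction of their included blocks
#' classified correctly. Estimates subject-level generalization of a fixed
#' configuration.
#'
#' @param spectra A [cohort_spectra()] object.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return List with `per_participant` (data.frame: participant_id, label,
#'   n_blocks, accuracy), `mean`, `sd`.
#' @export
loocv_by_participant <- function(spectra, config, seed = 1L) {
  feats <- bin_features(spectra, config$setting)
  pt <- participant_table(feats$meta)
  if (nrow(pt) < 2) stop_param("need >= 2 participants")
  acc <- vapply(seq_len(nrow(pt)), function(i) {
    te <- feats$meta$participant_id == pt$participant_id[i]
    if (!any(te)) return(NA_real_)
    pred <- fit_predict(feats$x[!te, , drop = FALSE],
                        feats$meta$label[!te],
                        feats$x[te, , drop = FALSE], config,
                        seed = derive_seed(seed, i))
    mean(pred$predicted == feats$meta$label[te])
  }, numeric(1))
  per <- data.frame(participant_id = pt$participant_id, label = pt$label,
                    n_blocks = as.integer(table(
                      factor(feats$meta$participant_id,
                             levels = pt$participant_id))),
                    accuracy = acc, stringsAsFactors = FALSE)
  ok <- !is.na(acc)
  list(per_participant = per, mean = mean(acc[ok]), sd = stats::sd(acc[ok]))
}

# Trapezoidal AUC over the empirical ROC of the scores (AF positive).
auc_trapezoid <- function(score, truth) {
  pos <- truth == "AF"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  p <- pos[ord]
  # cumulative counts at each distinct threshold
  dup <- rev(duplicated(rev(s)))        # keep last index of each tie group
  tpr <- c(0, cumsum(p)[!dup] / n1, 1)
  fpr <- c(0, cumsum(!p)[!dup] / n0, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Confusion-matrix evaluation of block predictions
#'
#' Treats AF as the positive class and reports accuracy, recall
#' (sensitivity), specificity, precision, F1 (`2*recall*precision /
#' (recall+precision)`) and the trapezoidal ROC AUC of the scores. Metrics
#' whose denominator is empty (e.g. recall with no AF blocks) are `NA` with a
#' warning; AUC is `NA` when only one class is present. Values are kept at
#' full precision; round only at reporting time with [format_report()].
#'
#' @param predicted Predicted labels (`"AF"`/`"NON_AF"`).
#' @param truth True labels.
#' @param score Optional AF scores for the AUC.
#' @return List of class `eval_report`: tp, fp, tn, fn, accuracy, recall,
#'   specificity, precision, f1, auc, n.
#' @export
evaluate <- function(predicted, truth, score = NULL) {
  if (!length(predicted)) stop_param("no predictions to evaluate")
  if (length(predicted) != length(truth)) stop_param("length mismatch")
  tp <- sum(predicted == "AF" & truth == "AF")
  fp <- sum(predicted == "AF" & truth == "NON_AF")
  tn <- sum(predicted == "NON_AF" & truth == "NON_AF")
  fn <- sum(predicted == "NON_AF" & truth == "AF")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator)", call. = FALSE)
      NA_real_
    } else num / den
  }
  recall <- safe_div(tp, tp + fn, "recall")
  specificity <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0)
    NA_real_ else 2 * recall * precision / (recall + precision)
  auc <- if (is.null(score)) NA_real_ else {
    a <- auc_trapezoid(score, truth)
    if (is.na(a)) warning("AUC undefined: only one class present",
                          call. = FALSE)
    a
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(truth),
                 recall = recall, specificity = specificity,
                 precision = precision, f1 = f1, auc = auc,
                 n = length(truth)),
            class = "eval_report")
}

#' Round an evaluation report for tabulation
#'
#' @param report An `eval_report`.
#' @param digits Decimal places (half rounds away from zero, the convention
#'   of printed clinical tables).
#' @return Named numeric vector of the six rounded metrics.
#' @export
format_report <- function(report, digits = 2) {
  m <- c(accuracy = report$accuracy, recall = report$recall,
         specificity = report$specificity, precision = report$precision,
         f1 = report$f1, auc = report$auc)
  round_half_up(m, digits)
}

#' Train a final model on every included block of a cohort
#'
#' @param spectra A [cohort_spectra()] object.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return A `bcg_model` carrying its featurization setting.
#' @export
train_model <- function(spectra, config, seed = 1L) {
  feats <- bin_features(spectra, config$setting)
  fit_classifier(feats$x, feats$meta$label, config, seed)
}

#' Score every included block of a cohort with a fitted model
#'
#' The blocks are featurized under the model's own setting, so a model can be
#' applied unchanged to data from any sensor placement.
#'
#' @param model A `bcg_model`.
#' @param spectra A [cohort_spectra()] object.
#' @return data.frame: block identity columns plus `predicted` and `score`.
#' @export
apply_model <- function(model, spectra) {
  feats <- bin_features(spectra, model$config$setting)
  pred <- predict_af_score(model, feats$x)
  out <- feats$meta[, c("participant_id", "placement", "start_sample",
                        "label")]
  out$predicted <- ifelse(pred >= 0.5, "AF", "NON_AF")
  out$score <- pred
  rownames(out) <- NULL
  out
}

#' Cross-location robustness evaluation
#'
#' Applies one placement's fitted model to test blocks recorded at each
#' requested placement (features computed under the model's setting) and
#' reports the full metric panel per placement — the sensor-shift robustness
#' grid.
#'
#' @param model A `bcg_model` (trained on one placement).
#' @param spectra Test-cohort [cohort_spectra()] covering the placements.
#' @param placements Placements to evaluate on.
#' @return data.frame with one row per placement: n, accuracy, recall,
#'   specificity, precision, f1, auc.
#' @export
cross_location_apply <- function(model, spectra,
                                 placements = names(sensor_placements())) {
  rows <- lapply(placements, function(pl) {
    sub <- spectra
    keep <- sub$meta$placement == pl
    if (!any(keep)) stop_param("no blocks for placement ", pl)
    sub$meta <- sub$meta[keep, , drop = FALSE]
    preds <- apply_model(model, sub)
    rep_ <- evaluate(preds$predicted, preds$label, preds$score)
    data.frame(placement = pl, n = rep_$n, accuracy = rep_$accuracy,
               recall = rep_$recall, specificity = rep_$specificity,
               precision = rep_$precision, f1 = rep_$f1, auc = rep_$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
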