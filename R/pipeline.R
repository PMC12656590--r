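#' Default end-to-end pipeline configuration
#'
#' The cohort sizes mirror the study design this pipeline implements: 67
#' training/validation participants (23 AF / 44 non-AF) and 17 held-out test
#' participants (6 AF / 11 non-AF), 5-minute recordings at 500 Hz, training
#' on the chest-level sensor (BCG2). The tuning grid is a compact
#' neighbourhood of the known-good region (AdaBoost with 0-10 Hz / 30-bin
#' style featurizations, plus one representative of each other family) so a
#' full run stays desk-scale; pass `grid = default_grid()` to
#' [run_pipeline()] for the exhaustive search.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(n_af_train = 23, n_non_af_train = 44,
                    n_af_test = 6, n_non_af_test = 11,
                    duration_s = 300),
    featurize = list(train_placement = "BCG2",
                     placements = names(sensor_placements()),
                     threshold = 34000, max_freq = 40),
    train = list(k = 5),
    fuse = list(subsets = NULL)   # NULL = all 15 non-empty subsets
  )
}

#' Compact tuning grid around the known-good configuration region
#'
#' @return List of [classifier_config()]s.
#' @export
reduced_grid <- function() {
  s_0_10_30 <- spectrum_setting(0, 10, 30)
  s_1_10_50 <- spectrum_setting(1, 10, 50)
  s_12_20_10 <- spectrum_setting(1.2, 20, 10)
  list(
    classifier_config("DT", s_0_10_30, max_depth = 3),
    classifier_config("RF", s_1_10_50, max_depth = 10),
    classifier_config("LR", s_0_10_30, C = 1),
    classifier_config("ADA", s_0_10_30, max_depth = 7, learning_rate = 0.9),
    classifier_config("ADA", s_0_10_30, max_depth = 1, learning_rate = 0.8),
    classifier_config("ADA", s_1_10_50, max_depth = 7, learning_rate = 0.9),
    classifier_config("ADA", s_12_20_10, max_depth = 2, learning_rate = 1.0)
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in order: cohort simulation, preprocessing and
#' spectral featurization, grid search with participant-grouped stratified
#' five-fold cross-validation, final-model training, test-set evaluation,
#' cross-location application, and OR-rule sensor fusion. When `out_dir` is
#' given, every intermediate artifact (cohorts, features, CV table,
#' predictions, reports) is written as CSV/JSON together with a run
#' manifest; rerunning with the same seed reproduces the artifacts
#' byte-identically.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory.
#' @param grid Tuning grid; defaults to [reduced_grid()].
#' @param params [synth_params()] for the simulator.
#' @return List with `train_spectra`, `test_spectra`, `search`, `model`,
#'   `test_report`, `cross_location`, `fusion`, `participant_acc`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         grid = reduced_grid(),
                         params = synth_params(
                           duration_s = config$simulate$duration_s)) {
  seed <- config$seed
  sim <- config$simulate
  fz <- config$featurize

  train_cohort <- generate_cohort(sim$n_af_train, sim$n_non_af_train,
                                  params, seed = derive_seed(seed, 1),
                                  id_prefix = "TR")
  test_cohort <- generate_cohort(sim$n_af_test, sim$n_non_af_test,
                                 params, seed = derive_seed(seed, 2),
                                 id_prefix = "TE")
  if (!length(train_cohort) || !length(test_cohort))
    stop_param("simulate stage produced an empty cohort")

  train_spectra <- cohort_spectra(train_cohort, fz$train_placement,
                                  fz$threshold, fz$max_freq)
  test_spectra <- cohort_spectra(test_cohort, fz$placements,
                                 fz$threshold, fz$max_freq)

  search <- grid_search(train_spectra, grid, k = config$train$k,
                        seed = derive_seed(seed, 3))
  model <- train_model(train_spectra, search$best,
                       seed = derive_seed(seed, 4))

  own <- test_spectra
  own$meta <- own$meta[own$meta$placement == fz$train_placement, ,
                       drop = FALSE]
  own_preds <- apply_model(model, own)
  test_report <- evaluate(own_preds$predicted, own_preds$label,
                          own_preds$score)

  cross <- cross_location_apply(model, test_spectra, fz$placements)

  preds_by_sensor <- lapply(fz$placements, function(pl) {
    sub <- test_spectra
    sub$meta <- sub$meta[sub$meta$placement == pl, , drop = FALSE]
    apply_model(model, sub)
  })
  names(preds_by_sensor) <- fz$placements
  total_blocks <- length(test_cohort) *
    n_blocks_expected(round(sim$duration_s * params$fs))
  fusion <- fusion_table(preds_by_sensor, config$fuse$subsets, total_blocks)
  part_acc <- participant_accuracy(own_preds)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(train_cohort, file.path(out_dir, "train_cohort"))
    write_cohort(test_cohort, file.path(out_dir, "test_cohort"))
    feats <- bin_features(train_spectra, search$best$setting)
    write_features_csv(feats, file.path(out_dir, "train_features.csv"))
    utils::write.csv(search$cv, file.path(out_dir, "cv_results.csv"),
                     row.names = FALSE)
    utils::write.csv(own_preds, file.path(out_dir, "test_predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(cross, file.path(out_dir, "cross_location.csv"),
                     row.names = FALSE)
    utils::write.csv(fusion, file.path(out_dir, "fusion.csv"),
                     row.names = FALSE)
    utils::write.csv(part_acc,
                     file.path(out_dir, "participant_accuracy.csv"),
                     row.names = FALSE)
    write_report_json(test_report, file.path(out_dir, "test_report.json"))
    arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- run_manifest(seed, config,
                             arts[!grepl("manifest", arts)])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(train_spectra = train_spectra, test_spectra = test_spectra,
       search = search, model = model, test_report = test_report,
       cross_location = cross, fusion = fusion,
       participant_acc = part_acc, manifest = manifest)
}
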