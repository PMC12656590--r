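#' Decision-level OR-rule fusion of per-sensor block predictions
#'
#' The four channels are recorded simultaneously, so blocks align exactly by
#' `(participant_id, start_sample)`. For each aligned block, only the sensors
#' in `subset` whose window passed noise rejection contribute; the fused
#' label is AF if any available prediction is AF. A block is dropped only
#' when no sensor in the subset has a prediction — which is why combining
#' sensors recovers blocks that a single noisy channel would lose.
#'
#' @param predictions_by_sensor Named list (placement -> data.frame from
#'   [apply_model()]: participant_id, start_sample, label, predicted, score).
#' @param subset Character vector of placements to fuse.
#' @return data.frame: participant_id, start_sample, label, n_available,
#'   predicted, score (max available score).
#' @export
combine_or <- function(predictions_by_sensor, subset) {
  if (!length(subset)) stop_param("sensor subset must be non-empty")
  missing_pl <- setdiff(subset, names(predictions_by_sensor))
  if (length(missing_pl))
    stop_param("no predictions for placement(s): ",
               paste(missing_pl, collapse = ", "))
  pooled <- do.call(rbind, lapply(subset, function(pl) {
    p <- predictions_by_sensor[[pl]]
    p[, c("participant_id", "start_sample", "label", "predicted", "score")]
  }))
  key <- paste(pooled$participant_id, pooled$start_sample)
  split_idx <- split(seq_len(nrow(pooled)), key)
  rows <- lapply(split_idx, function(ix) {
    sub <- pooled[ix, , drop = FALSE]
    data.frame(participant_id = sub$participant_id[1],
               start_sample = sub$start_sample[1],
               label = sub$label[1],
               n_available = nrow(sub),
               predicted = if (any(sub$predicted == "AF")) "AF" else
                 "NON_AF",
               score = max(sub$score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$start_sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a fused prediction set
#'
#' Standard confusion-matrix evaluation of the fused labels plus the number
#' and percentage of blocks retained out of the cohort total — the quantity
#' that shows how multi-sensor fusion reduces noise exclusion.
#'
#' @param fused Output of [combine_or()].
#' @param total_blocks Total aligned blocks in the cohort (the inclusion
#'   denominator).
#' @return List with `report` (an `eval_report`), `included_n`,
#'   `included_pct`.
#' @export
fusion_report <- function(fused, total_blocks) {
  rep_ <- evaluate(fused$predicted, fused$label, fused$score)
  list(report = rep_, included_n = nrow(fused),
       included_pct = 100 * nrow(fused) / total_blocks)
}

#' Fusion reports over a lattice of sensor subsets
#'
#' @param predictions_by_sensor As in [combine_or()].
#' @param subsets List of placement vectors; defaults to all 15 non-empty
#'   subsets of the four sensors.
#' @param total_blocks Inclusion denominator.
#' @return data.frame, one row per subset: subset, included_n, included_pct,
#'   and the metric panel.
#' @export
fusion_table <- function(predictions_by_sensor,
                         subsets = NULL, total_blocks) {
  pls <- names(sensor_placements())
  if (is.null(subsets)) {
    subsets <- list()
    for (m in 1:4) subsets <- c(subsets, utils::combn(pls, m,
                                                      simplify = FALSE))
  }
  rows <- lapply(subsets, function(s) {
    fr <- fusion_report(combine_or(predictions_by_sensor, s), total_blocks)
    data.frame(subset = paste(s, collapse = "+"),
               included_n = fr$included_n,
               included_pct = fr$included_pct,
               accuracy = fr$report$accuracy, recall = fr$report$recall,
               specificity = fr$report$specificity,
               precision = fr$report$precision, f1 = fr$report$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participant-level accuracy of block predictions
#'
#' For each participant, the fraction of their included blocks whose
#' predicted label matches the participant's rhythm label (for AF
#' participants the fraction predicted AF; for non-AF the fraction predicted
#' non-AF).
#'
#' @param predictions data.frame with `participant_id`, `label`,
#'   `predicted`.
#' @return data.frame: participant_id, label, n_blocks, accuracy.
#' @export
participant_accuracy <- function(predictions) {
  if (!nrow(predictions)) stop_param("no predictions")
  ids <- unique(predictions$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- predictions[predictions$participant_id == id, , drop = FALSE]
    data.frame(participant_id = id, label = sub$label[1],
               n_blocks = nrow(sub),
               accuracy = mean(sub$predicted == sub$label),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
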