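#' Continuous sliding-window probability trace
#'
#' Runs the detector at every stride position over the whole recording (no
#' latency exclusion at inference time: exclusion is a training-set rule
#' only). Timestamps are window END times, so the value at time t uses only
#' samples up to t — detection never looks into the future.
#'
#' @param object A fitted [pges_detector()].
#' @param mrec An `eeg_montaged` recording at the detector's sampling rate.
#' @param spec [crop_spec()] giving window and stride; defaults to the
#'   detector's training spec.
#' @param batch_size Windows materialized per prediction batch (memory
#'   control only; results are batch-size independent).
#' @return A `pges_trace`: list with `recording_id`, `times_s` (window end
#'   times, strictly increasing at the stride), `probs`, `spec`, and the
#'   true `pges_end_s` when the recording carries one.
#' @export
probability_trace <- function(object, mrec, spec = NULL, batch_size = 256L) {
  stopifnot(inherits(object, "pges_detector"), inherits(mrec, "eeg_montaged"))
  if (is.null(spec)) spec <- object$spec
  fs <- mrec$sampling_rate_hz
  if (abs(fs - object$sampling_rate_hz) > 1e-9)
    stop("recording rate ", fs, " Hz differs from the detector's ",
         object$sampling_rate_hz, " Hz; resample first")
  n_win <- count_crops(mrec$duration_s, spec)
  if (n_win < 1) stop("recording shorter than one window")
  w_n <- round(spec$window_s * fs)
  starts <- (seq_len(n_win) - 1L) * spec$stride_s
  probs <- numeric(n_win)
  for (at in seq(1L, n_win, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n_win)
    data <- array(0, dim = c(nrow(mrec$data), w_n, length(idx)))
    for (j in seq_along(idx)) {
      s0 <- round(starts[idx[j]] * fs)
      data[, , j] <- mrec$data[, (s0 + 1):(s0 + w_n), drop = FALSE]
    }
    batch <- structure(list(data = data,
                            index = data.frame(
                              recording_id = mrec$recording_id,
                              start_s = starts[idx],
                              end_s = starts[idx] + spec$window_s,
                              label = NA_integer_),
                            spec = spec, sampling_rate_hz = fs,
                            montage_labels = mrec$montage_labels),
                       class = "pges_crops")
    probs[idx] <- predict(object, batch)
  }
  structure(list(recording_id = mrec$recording_id,
                 times_s = starts + spec$window_s, probs = probs,
                 spec = spec, pges_end_s = mrec$pges_end_s),
            class = "pges_trace")
}

#' @export
print.pges_trace <- function(x, ...) {
  cat("<pges_trace> ", x$recording_id, ": ", length(x$times_s),
      " probabilities every ", x$spec$stride_s, " s from t = ",
      x$times_s[1], " s\n", sep = "")
  invisible(x)
}

#' Onset-calling rule for probability traces
#'
#' The paper's models output probabilities; turning a trace into a single
#' detection time requires a rule. The rule used here calls the end of
#' suppression at the earliest grid time where the probability reaches
#' `threshold` and stays there for `k_consecutive` grid points.
#'
#' @param threshold Probability threshold in (0, 1), default 0.5.
#' @param k_consecutive Required consecutive super-threshold points
#'   (default 3, i.e. 300 ms at the default stride).
#' @return List of class `pges_onset_rule`.
#' @export
onset_rule <- function(threshold = 0.5, k_consecutive = 3L) {
  stopifnot(threshold > 0, threshold < 1, k_consecutive >= 1)
  structure(list(threshold = threshold,
                 k_consecutive = as.integer(k_consecutive)),
            class = "pges_onset_rule")
}

#' Call the detection time from a probability trace
#'
#' @param trace A `pges_trace`.
#' @param rule An [onset_rule()].
#' @return List with `recording_id`, `detected_s` (earliest grid time whose
#'   next `k_consecutive` probabilities are all at or above the threshold;
#'   `NA` if never) and the rule used.
#' @export
detect_onset <- function(trace, rule = onset_rule()) {
  stopifnot(inherits(trace, "pges_trace"), inherits(rule, "pges_onset_rule"))
  above <- trace$probs >= rule$threshold
  k <- rule$k_consecutive
  detected <- NA_real_
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= k)
    if (length(hit))
      detected <- trace$times_s[ends[hit[1]] - r$lengths[hit[1]] + 1L]
  }
  list(recording_id = trace$recording_id, detected_s = detected,
       rule = rule)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly drawn positive crop outscores a
#' uniformly drawn negative crop, with ties counted one half — computed via
#' average ranks.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
crop_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes in `labels`")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Latency-aware cohort evaluation
#'
#' Reproduces the study's evaluation protocol on annotated test recordings:
#' pooled per-crop AUC over the training-rule crop sets of all test
#' recordings (with per-recording AUC as a secondary column), plus
#' per-recording onset detection. A recording is detected correctly when a
#' detection exists and falls inside `[pges_end_s, pges_end_s + latency_s]`;
#' a detection before the true end is a false alarm and counts as incorrect,
#' as does no detection at all.
#'
#' @param object A fitted [pges_detector()].
#' @param recordings List of annotated `eeg_montaged` recordings.
#' @param spec [crop_spec()]; defaults to the detector's training spec. Its
#'   `stride_s` sets the inference grid; `latency_s` bounds timely
#'   detection.
#' @param rule An [onset_rule()].
#' @return A `pges_eval` object: list with `auc` (pooled), `auc_by_recording`
#'   (mean of per-recording AUCs over recordings holding both classes),
#'   `detection_rate`, `false_alarm_rate`, `median_latency_s`,
#'   `iqr_latency_s` and the `per_recording` data frame.
#' @export
evaluate_cohort <- function(object, recordings, spec = NULL,
                            rule = onset_rule()) {
  stopifnot(inherits(object, "pges_detector"), length(recordings) >= 1)
  if (is.null(spec)) spec <- object$spec
  annotated <- vapply(recordings, function(r) !is.null(r$pges_end_s), TRUE)
  if (!any(annotated)) stop("no annotated recordings to evaluate")
  recordings <- recordings[annotated]

  scores_all <- numeric(0)
  labels_all <- integer(0)
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    mrec <- recordings[[i]]
    crops <- enumerate_crops(mrec, spec)
    p <- predict(object, crops)
    scores_all <- c(scores_all, p)
    labels_all <- c(labels_all, crops$index$label)
    rec_auc <- if (length(unique(crops$index$label)) == 2)
      crop_auc(p, crops$index$label) else NA_real_

    tr <- probability_trace(object, mrec, spec)
    det <- detect_onset(tr, rule)
    err <- det$detected_s - mrec$pges_end_s
    rows[[i]] <- data.frame(
      recording_id = mrec$recording_id,
      true_end_s = mrec$pges_end_s,
      detected_s = det$detected_s,
      latency_error_s = err,
      correct = !is.na(det$detected_s) && err >= 0 &&
        err <= spec$latency_s,
      false_alarm = !is.na(det$detected_s) && err < 0,
      crop_auc = rec_auc,
      stringsAsFactors = FALSE)
  }
  per_rec <- do.call(rbind, rows)
  errs <- per_rec$latency_error_s[per_rec$correct]
  structure(list(
    auc = crop_auc(scores_all, labels_all),
    auc_by_recording = mean(per_rec$crop_auc, na.rm = TRUE),
    detection_rate = mean(per_rec$correct),
    false_alarm_rate = mean(per_rec$false_alarm),
    median_latency_s = if (length(errs)) stats::median(errs) else NA_real_,
    iqr_latency_s = if (length(errs)) stats::IQR(errs) else NA_real_,
    n_recordings = nrow(per_rec),
    n_crops = length(labels_all),
    rule = rule, spec = spec,
    per_recording = per_rec), class = "pges_eval")
}

#' @export
print.pges_eval <- function(x, ...) {
  cat("<pges_eval> ", x$n_recordings, " recordings, ", x$n_crops,
      " crops\n", sep = "")
  cat(sprintf("  pooled crop AUC        %.4f\n", x$auc))
  cat(sprintf("  mean per-recording AUC %.4f\n", x$auc_by_recording))
  cat(sprintf("  detection rate (<= %g s late) %.3f\n",
              x$spec$latency_s, x$detection_rate))
  cat(sprintf("  false alarm rate       %.3f\n", x$false_alarm_rate))
  if (!is.na(x$median_latency_s))
    cat(sprintf("  latency of correct detections: median %.2f s, IQR %.2f s\n",
                x$median_latency_s, x$iqr_latency_s))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param ev A `pges_eval` object.
#' @param dir Output directory; writes `report.json` (aggregates) and
#'   `per_recording.csv`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(ev, dir) {
  stopifnot(inherits(ev, "pges_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  agg <- ev[c("auc", "auc_by_recording", "detection_rate",
              "false_alarm_rate", "median_latency_s", "iqr_latency_s",
              "n_recordings", "n_crops")]
  jsonlite::write_json(agg, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(ev$per_recording, file.path(dir, "per_recording.csv"),
                   row.names = FALSE)
  invisible(dir)
}
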