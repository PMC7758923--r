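#' Sliding-window crop specification
#'
#' Window length, stride and detection latency, in seconds. Defaults are the
#' operating point used for real-time review: a 10 s window advanced every
#' 100 ms, with detections accepted up to 10 s after the true end of
#' suppression.
#'
#' @param window_s Window length (default 10).
#' @param stride_s Stride between window starts (default 0.1).
#' @param latency_s Accepted detection latency after the true end (default 10).
#' @return A list of class `pges_crop_spec`.
#' @export
crop_spec <- function(window_s = 10, stride_s = 0.1, latency_s = 10) {
  if (!(window_s > stride_s && stride_s > 0))
    stop("need window_s > stride_s > 0")
  if (latency_s <= 0) stop("latency_s must be positive")
  structure(list(window_s = window_s, stride_s = stride_s,
                 latency_s = latency_s),
            class = "pges_crop_spec")
}

#' Number of sliding windows that fit in a segment
#'
#' Windows start at 0, `stride_s`, `2 * stride_s`, ... and must lie entirely
#' within the segment: the count is
#' `floor((segment_len_s - window_s) / stride_s) + 1` when the segment holds
#' at least one window, otherwise 0.
#'
#' @param segment_len_s Segment length in seconds (>= 0).
#' @param spec A [crop_spec()].
#' @return Nonnegative integer count.
#' @export
count_crops <- function(segment_len_s, spec = crop_spec()) {
  stopifnot(segment_len_s >= 0)
  if (segment_len_s < spec$window_s - 1e-9) return(0L)
  # guard the floor() against representation error in (len - w) / stride
  as.integer(floor((segment_len_s - spec$window_s) / spec$stride_s + 1e-9)) + 1L
}

#' Label a crop against the annotated end of suppression
#'
#' A crop is positive when it reaches or passes the end of PGES: label 1 iff
#' the crop's end time is at or after `pges_end_s` (inclusive boundary),
#' otherwise 0 (the crop lies inside suppression).
#'
#' @param end_s Crop end time in seconds.
#' @param pges_end_s Annotated end of suppression in seconds.
#' @return 0 or 1 (integer).
#' @export
label_crop <- function(end_s, pges_end_s) {
  stopifnot(is.finite(end_s), is.finite(pges_end_s))
  as.integer(end_s >= pges_end_s - 1e-9)
}

#' Enumerate labeled crops from an annotated montaged recording
#'
#' Windows start on the grid 0, stride, 2*stride, ... Crops whose end lies
#' beyond `pges_end_s + latency_s` are excluded entirely: no content past
#' the accepted latency period enters the training set, and the retained
#' count equals `count_crops(min(duration_s, pges_end_s + latency_s), spec)`.
#' Retained crops are labeled with [label_crop()].
#'
#' @param mrec An annotated `eeg_montaged` recording (needs `pges_end_s`).
#' @param spec A [crop_spec()].
#' @return A `pges_crops` object: list with `data` (array channels x
#'   samples x crops), `index` (data frame recording_id, start_s, end_s,
#'   label) and `spec`.
#' @export
enumerate_crops <- function(mrec, spec = crop_spec()) {
  stopifnot(inherits(mrec, "eeg_montaged"))
  if (is.null(mrec$pges_end_s))
    stop("recording ", mrec$recording_id,
         " has no pges_end_s annotation; crops cannot be labeled")
  fs <- mrec$sampling_rate_hz
  w_n <- round(spec$window_s * fs)
  if (mrec$duration_s < spec$window_s - 1e-9)
    stop("recording shorter than one window")
  horizon <- min(mrec$duration_s, mrec$pges_end_s + spec$latency_s)
  n_keep <- count_crops(horizon, spec)
  starts <- (seq_len(n_keep) - 1L) * spec$stride_s
  ends <- starts + spec$window_s
  data <- array(0, dim = c(nrow(mrec$data), w_n, n_keep))
  for (i in seq_len(n_keep)) {
    s0 <- round(starts[i] * fs)
    data[, , i] <- mrec$data[, (s0 + 1):(s0 + w_n), drop = FALSE]
  }
  index <- data.frame(recording_id = rep(mrec$recording_id, n_keep),
                      start_s = starts,
                      end_s = ends,
                      label = vapply(ends, label_crop, 0L,
                                     pges_end_s = mrec$pges_end_s),
                      stringsAsFactors = FALSE)
  structure(list(data = data, index = index, spec = spec,
                 sampling_rate_hz = fs,
                 montage_labels = mrec$montage_labels),
            class = "pges_crops")
}

#' @export
print.pges_crops <- function(x, ...) {
  cat("<pges_crops> ", nrow(x$index), " crops from ",
      length(unique(x$index$recording_id)), " recording(s); ",
      sum(x$index$label), " positive\n", sep = "")
  cat("  window ", x$spec$window_s, " s, stride ", x$spec$stride_s,
      " s, latency ", x$spec$latency_s, " s at ", x$sampling_rate_hz,
      " Hz\n", sep = "")
  invisible(x)
}

#' Combine crop sets from several recordings
#'
#' @param ... `pges_crops` objects sharing a spec, rate and montage.
#' @return A single `pges_crops` object.
#' @export
bind_crops <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "pges_crops"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "pges_crops")))
  fs <- sets[[1]]$sampling_rate_hz
  if (any(vapply(sets, function(s) s$sampling_rate_hz, 0) != fs))
    stop("crop sets have mixed sampling rates")
  dims <- vapply(sets, function(s) dim(s$data)[1:2], numeric(2))
  if (any(dims != dims[, 1]))
    stop("crop sets have mismatched channel/sample dimensions")
  n_tot <- sum(vapply(sets, function(s) dim(s$data)[3], 0))
  data <- array(0, dim = c(dims[1, 1], dims[2, 1], n_tot))
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[3]
    data[, , at + seq_len(k)] <- s$data
    at <- at + k
  }
  structure(list(data = data,
                 index = do.call(rbind, lapply(sets, `[[`, "index")),
                 spec = sets[[1]]$spec, sampling_rate_hz = fs,
                 montage_labels = sets[[1]]$montage_labels),
            class = "pges_crops")
}

#' Leakage-safe recording-level train/test split
#'
#' Recordings (hence every crop they contain) are assigned wholly to one
#' side. The train size is `floor(train_fraction * n)`, which reproduces the
#' 134/34 partition of a 168-recording cohort at 80/20. Shuffling is seeded.
#'
#' @param recording_ids Character vector of ids (nonempty, unique).
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` id vectors.
#' @export
split_recordings <- function(recording_ids, train_fraction = 0.8, seed = 1) {
  if (length(recording_ids) == 0) stop("recording_ids is empty")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly in (0, 1)")
  set.seed(as.integer(seed %% .Machine$integer.max))
  ids <- sample(recording_ids)
  n_train <- floor(train_fraction * length(ids))
  list(train = sort(ids[seq_len(n_train)]),
       test = sort(ids[-seq_len(n_train)]))
}
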