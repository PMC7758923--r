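#' Default longitudinal bipolar montage
#'
#' The ten standard adjacent-electrode pairs used for PGES review:
#' Fp1-F7, F7-T7, T7-P7, P7-O1, Fp2-F8, F8-T8, T8-P8, P8-O2, Fz-Cz, Cz-Pz.
#'
#' @return Data frame with columns `anode` and `cathode`, one row per pair.
#' @export
default_montage_pairs <- function() {
  data.frame(
    anode   = c("Fp1", "F7", "T7", "P7", "Fp2", "F8", "T8", "P8", "Fz", "Cz"),
    cathode = c("F7", "T7", "P7", "O1", "F8", "T8", "P8", "O2", "Cz", "Pz"),
    stringsAsFactors = FALSE)
}

new_montaged <- function(recording_id, montage_labels, data, sampling_rate_hz,
                         pges_end_s) {
  rownames(data) <- montage_labels
  structure(
    list(recording_id = recording_id,
         montage_labels = montage_labels,
         data = data,
         sampling_rate_hz = sampling_rate_hz,
         duration_s = ncol(data) / sampling_rate_hz,
         pges_end_s = pges_end_s),
    class = "eeg_montaged")
}

#' @export
print.eeg_montaged <- function(x, ...) {
  cat("<eeg_montaged> ", x$recording_id, ": ", length(x$montage_labels),
      " bipolar channels, ", format(x$duration_s), " s at ",
      format(x$sampling_rate_hz), " Hz\n", sep = "")
  if (!is.null(x$pges_end_s))
    cat("  PGES end annotated at ", format(x$pges_end_s), " s\n", sep = "")
  invisible(x)
}

#' Derive a bipolar montage from a referential recording
#'
#' Each montage channel is the samplewise difference between an anode and a
#' cathode electrode (`anode - cathode`), the standard bipolar derivation
#' used in clinical EEG review. The annotation and sampling rate are carried
#' through unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param pairs Data frame with columns `anode` and `cathode`; defaults to
#'   the ten pairs of [default_montage_pairs()].
#' @return An `eeg_montaged` object whose rows are labelled
#'   `"anode-cathode"`.
#' @export
to_bipolar_montage <- function(rec, pairs = default_montage_pairs()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(c("anode", "cathode") %in% names(pairs)))
    stop("pairs must have columns anode and cathode")
  if (any(pairs$anode == pairs$cathode))
    stop("montage pair with identical anode and cathode")
  labels <- paste0(pairs$anode, "-", pairs$cathode)
  if (anyDuplicated(labels))
    stop("duplicate montage pair: ", labels[duplicated(labels)][1])
  referenced <- unique(c(pairs$anode, pairs$cathode))
  missing <- setdiff(referenced, rec$channel_labels)
  if (length(missing))
    stop("electrode(s) not present in recording: ",
         paste(missing, collapse = ", "))
  data <- rec$data[pairs$anode, , drop = FALSE] -
    rec$data[pairs$cathode, , drop = FALSE]
  new_montaged(rec$recording_id, labels, data, rec$sampling_rate_hz,
               rec$pges_end_s)
}

# best rational p/q approximation of x with q bounded (continued fractions)
rational_approx <- function(x, max_den = 4096L) {
  a <- floor(x); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1; frac <- x - a
  while (frac > 1e-12 && q1 < max_den) {
    x <- 1 / frac; a <- floor(x); frac <- x - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(p = p1, q = q1)
}

#' Resample a montaged recording to a uniform rate
#'
#' Band-limited polyphase rational resampling with anti-aliasing, used to
#' align mixed acquisition rates (clinically 150-256 Hz) onto one grid
#' (200 Hz by default). The output is trimmed or edge-padded to exactly
#' `round(duration_s * target_rate_hz)` samples; annotation times are in
#' seconds and are unchanged.
#'
#' @param mrec An `eeg_montaged` object.
#' @param target_rate_hz Target sampling rate, default 200.
#' @return An `eeg_montaged` object at the target rate.
#' @export
resample_montage <- function(mrec, target_rate_hz = 200) {
  stopifnot(inherits(mrec, "eeg_montaged"))
  if (!is.numeric(target_rate_hz) || length(target_rate_hz) != 1L ||
      target_rate_hz <= 0)
    stop("target_rate_hz must be a positive scalar")
  fs <- mrec$sampling_rate_hz
  if (fs < 50 || fs > 2000)
    stop("source rate ", fs, " Hz outside the supported 50-2000 Hz band")
  n_out <- round(mrec$duration_s * target_rate_hz)
  if (abs(fs - target_rate_hz) < 1e-9) {
    data <- mrec$data
  } else {
    pq <- rational_approx(target_rate_hz / fs)
    data <- t(apply(mrec$data, 1, function(x) {
      y <- signal::resample(x, pq["p"], pq["q"])
      if (length(y) >= n_out) y[seq_len(n_out)]
      else c(y, rep(y[length(y)], n_out - length(y)))
    }))
  }
  new_montaged(mrec$recording_id, mrec$montage_labels, data,
               target_rate_hz, mrec$pges_end_s)
}

#' Smooth montage channels with a unit-sum Hann window
#'
#' Zero-phase moving-average smoothing with a Hann (raised-cosine) kernel
#' normalized to unit sum, applied per channel with reflection padding at the
#' edges. Used as an optional denoising step before cropping; it preserves
#' constants and the per-channel mean and never amplifies broadband noise.
#'
#' @param mrec An `eeg_montaged` object.
#' @param window_len_samples Odd kernel length, at least 3. The default 11
#'   spans 55 ms at 200 Hz.
#' @return The smoothed `eeg_montaged` object.
#' @export
hann_denoise <- function(mrec, window_len_samples = 11L) {
  stopifnot(inherits(mrec, "eeg_montaged"))
  L <- window_len_samples
  if (length(L) != 1L || L < 3 || L %% 2 == 0)
    stop("window_len_samples must be an odd integer >= 3")
  k <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  k <- k / sum(k)
  h <- (L - 1) / 2
  data <- t(apply(mrec$data, 1, function(x) {
    n <- length(x)
    xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
    y <- stats::filter(xp, k, method = "convolution", sides = 2)
    y <- as.numeric(y[(h + 1):(h + n)])
    y + (mean(x) - mean(y))   # remove the edge-induced mean shift
  }))
  new_montaged(mrec$recording_id, mrec$montage_labels, data,
               mrec$sampling_rate_hz, mrec$pges_end_s)
}
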