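#' @useDynLib pgesdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 13 scalp electrodes used for PGES detection
#'
#' Standard 10-20 electrode labels from which the default bipolar montage is
#' derived.
#'
#' @return Character vector of 13 electrode names.
#' @export
pges_electrodes <- function() {
  c("Fp1", "Fp2", "O1", "O2", "F7", "F8", "T7", "T8",
    "P7", "P8", "Fz", "Cz", "Pz")
}

#' Construct an EEG recording object
#'
#' A recording holds a channels-by-samples matrix of scalp potentials in
#' microvolts, the electrode labels, the sampling rate, and (optionally) the
#' expert annotation of the end of postictal generalized EEG suppression
#' (PGES), in seconds from the start of the recording.
#'
#' @param recording_id Character scalar identifying the recording.
#' @param data Numeric matrix, one row per channel, amplitudes in microvolts.
#' @param channel_labels Character vector of electrode names, one per row.
#' @param sampling_rate_hz Positive sampling rate shared by all channels.
#' @param pges_end_s Optional nonnegative annotation of the end of
#'   suppression, in seconds; must not exceed the recording duration.
#' @return An object of class `eeg_recording` with fields `recording_id`,
#'   `channel_labels`, `data`, `sampling_rate_hz`, `duration_s`, `pges_end_s`.
#' @export
eeg_recording <- function(recording_id, data, channel_labels,
                          sampling_rate_hz, pges_end_s = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.character(channel_labels) || length(channel_labels) != nrow(data))
    stop("channel_labels must name every row of `data` (got ",
         length(channel_labels), " labels for ", nrow(data), " rows)")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "))
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive scalar")
  if (!all(is.finite(data))) stop("recording data contains non-finite values")
  duration_s <- ncol(data) / sampling_rate_hz
  if (!is.null(pges_end_s)) {
    if (!is.numeric(pges_end_s) || length(pges_end_s) != 1L ||
        !is.finite(pges_end_s) || pges_end_s < 0 || pges_end_s > duration_s)
      stop("pges_end_s must lie in [0, duration_s] = [0, ",
           format(duration_s), "]")
  }
  rownames(data) <- channel_labels
  structure(
    list(recording_id = as.character(recording_id),
         channel_labels = channel_labels,
         data = data,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         duration_s = duration_s,
         pges_end_s = if (is.null(pges_end_s)) NULL else as.numeric(pges_end_s)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$recording_id, "\n", sep = "")
  cat("  channels: ", length(x$channel_labels), " (",
      paste(utils::head(x$channel_labels, 6), collapse = ", "),
      if (length(x$channel_labels) > 6) ", ..." else "", ")\n", sep = "")
  cat("  ", format(x$duration_s), " s at ", format(x$sampling_rate_hz),
      " Hz (", ncol(x$data), " samples)\n", sep = "")
  if (!is.null(x$pges_end_s))
    cat("  PGES end annotated at ", format(x$pges_end_s), " s\n", sep = "")
  invisible(x)
}

#' Read a recording from the simple plain-text directory format
#'
#' The simple format is a directory holding `signals.csv` (comma-delimited
#' numeric matrix, one row per channel, no header) and `meta.json` with keys
#' `recording_id`, `channel_labels`, `sampling_rate_hz` and optionally
#' `pges_end_s`.
#'
#' @param dir Path to the directory.
#' @return An [eeg_recording()].
#' @export
read_simple_eeg <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  sig_path <- file.path(dir, "signals.csv")
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(sig_path)) stop("missing signals.csv in ", dir)
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("recording_id", "channel_labels", "sampling_rate_hz")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("meta.json lacks required keys: ", paste(missing, collapse = ", "))
  data <- as.matrix(utils::read.table(sig_path, sep = ",", header = FALSE))
  dimnames(data) <- NULL
  if (!is.numeric(data)) stop("signals.csv contains non-numeric entries")
  if (nrow(data) != length(meta$channel_labels))
    stop("shape mismatch: meta.json lists ", length(meta$channel_labels),
         " channels but signals.csv has ", nrow(data), " rows")
  eeg_recording(meta$recording_id, data, meta$channel_labels,
                meta$sampling_rate_hz,
                pges_end_s = meta$pges_end_s)
}

#' Write a recording in the simple plain-text directory format
#'
#' @param rec An [eeg_recording()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simple_eeg <- function(rec, dir) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rec$data, file.path(dir, "signals.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(recording_id = rec$recording_id,
               channel_labels = rec$channel_labels,
               sampling_rate_hz = rec$sampling_rate_hz)
  if (!is.null(rec$pges_end_s)) meta$pges_end_s <- rec$pges_end_s
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a PGES-end annotation sidecar
#'
#' @param path CSV file with columns `recording_id` and `pges_end_s`.
#' @return Data frame with one row per annotated recording.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "pges_end_s")
  if (!all(need %in% names(ann)))
    stop("annotation sidecar must have columns: ", paste(need, collapse = ", "))
  ann
}
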