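# EDF (European Data Format) 16-bit read/write.
# Layout: 256-byte fixed header, 256 bytes per signal header, then data
# records of little-endian int16 samples, channel-major within each record.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits using per-channel physical ranges set to
#' the channel's observed amplitude extremes, so a read back differs from the
#' original by at most one quantization step per sample. The data-record
#' duration is one second; recordings whose sample count is not a multiple of
#' the sampling rate are zero-padded to a whole record.
#'
#' @param rec An [eeg_recording()]. The sampling rate must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate; got ", fs)
  fs <- as.integer(round(fs))
  ns <- length(rec$channel_labels)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / fs)
  data <- rec$data
  if (n_rec * fs > n)
    data <- cbind(data, matrix(0, ns, n_rec * fs - n))

  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$recording_id, 80),
    pad_field(paste("Startdate 01-JAN-2000", rec$recording_id), 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256L * (1L + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1L, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", width = width),
                    collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(vapply(pmin, edf_num, "", width = 8), 8)
  field(vapply(pmax, edf_num, "", width = 8), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  # reparse the printed physical range so writer and reader share calibration
  pmin_h <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  scale <- (pmax_h - pmin_h) / (dmax - dmin)
  dig <- round(sweep(sweep(data, 1, pmin_h), 1, scale, "/")) + dmin
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF/EDF+ file
#'
#' Amplitudes are converted to physical units using the per-channel
#' physical/digital calibration in the header. All signals must share one
#' sampling rate; mixed-rate files are rejected (clinical scalp montage
#' channels share a rate, and the pipeline resamples whole recordings).
#'
#' @param path Path to an EDF file.
#' @param pges_end_s Optional PGES-end annotation (seconds) to attach; must
#'   lie within the recording.
#' @param channels Optional character vector: keep only these channels (in
#'   the order given). Other channels are dropped with a warning.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, pges_end_s = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("not a valid EDF file (version field '",
                                     version, "')")
  rd(80)                               # patient id
  recording_field <- rd(80)
  rd(8); rd(8)                         # date, time
  rd(8)                                # header bytes
  rd(44)                               # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("invalid EDF: bad signal count")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)                               # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))            # samples per record, per signal
  rdv(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr, n_rec, rec_dur)))
    stop("invalid EDF: unparseable numeric header field")
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported; ",
         "resample the source to a single rate first")
  fs <- spr[1] / rec_dur

  total <- n_rec * sum(spr)
  raw <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < total) stop("truncated EDF data section")
  data <- matrix(0, ns, n_rec * spr[1])
  dim(raw) <- c(spr[1], ns, n_rec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns))
    data[i, ] <- as.vector(raw[, i, ]) * scale[i] + pmin[i] - dmin[i] * scale[i]

  rec_id <- sub("^Startdate \\S+ ?", "", recording_field)
  if (!nzchar(rec_id)) rec_id <- tools::file_path_sans_ext(basename(path))
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing))
      stop("requested channels absent from EDF: ",
           paste(missing, collapse = ", "))
    extra <- setdiff(labels, channels)
    if (length(extra))
      warning("ignoring ", length(extra), " extra channel(s): ",
              paste(extra, collapse = ", "))
    keep <- match(channels, labels)
    data <- data[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  eeg_recording(rec_id, data, labels, fs, pges_end_s = pges_end_s)
}
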