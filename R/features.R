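# Per-crop feature bank: time-domain moments, periodogram-based spectral
# summaries (band power, power spectral intensity, peak/median frequency),
# Petrosian fractal dimension, SVD entropy, inter-channel correlation, and
# temporal first-half/second-half ratios.

#' Standard clinical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-70 Hz.
#'
#' @return Named list of two-element Hz intervals.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 70))
}

#' Time-domain moment features
#'
#' Population moments of a series: variance, skewness `m3 / m2^1.5` and
#' non-excess kurtosis `m4 / m2^2`. A constant series has variance 0 and its
#' skewness/kurtosis are undefined; they are returned as 0 with
#' `degenerate = TRUE`.
#'
#' @param series Numeric vector, length >= 4.
#' @return Named list: `variance`, `skewness`, `kurtosis`, `degenerate`.
#' @export
moment_features <- function(series) {
  stopifnot(length(series) >= 4)
  m <- mean(series)
  d <- series - m
  m2 <- mean(d^2)
  if (m2 < 1e-24)
    return(list(variance = 0, skewness = 0, kurtosis = 0, degenerate = TRUE))
  list(variance = m2,
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2,
       degenerate = FALSE)
}

# one-sided periodogram: frequencies and power (|fft|^2 / n), DC dropped
periodogram <- function(series, rate_hz) {
  n <- length(series)
  sp <- stats::fft(series)
  half <- floor(n / 2)
  idx <- 2:(half + 1)
  list(freq = (idx - 1) * rate_hz / n,
       power = Mod(sp[idx])^2 / n,
       amp = Mod(sp[idx]))
}

#' Spectral features of one series
#'
#' Periodogram-based: absolute and relative band power per band, power
#' spectral intensity (PSI: sum of spectral magnitudes over the band's
#' bins), peak frequency (argmax of power), median frequency (smallest
#' frequency where cumulative power reaches half the total) and total
#' energy. All-zero input yields zero powers and a degenerate flag.
#'
#' @param series Numeric vector covering at least ~2 s.
#' @param rate_hz Sampling rate in Hz.
#' @param bands Named list of Hz intervals, default [eeg_bands()]; bands are
#'   clipped at the Nyquist frequency and must keep at least one bin.
#' @return Named list of scalars (`power_<band>`, `psi_<band>`,
#'   `relpower_<band>`, `peak_freq`, `median_freq`, `total_energy`,
#'   `degenerate`).
#' @export
spectral_features <- function(series, rate_hz, bands = eeg_bands()) {
  stopifnot(length(series) >= 2 * rate_hz)
  pg <- periodogram(series, rate_hz)
  total <- sum(pg$power)
  out <- list()
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- min(bands[[b]][2], rate_hz / 2)
    sel <- pg$freq >= lo & pg$freq <= hi
    if (!any(sel))
      stop("band ", b, " maps to no periodogram bin at rate ", rate_hz)
    out[[paste0("power_", b)]] <- sum(pg$power[sel])
    out[[paste0("psi_", b)]] <- sum(pg$amp[sel])
    out[[paste0("relpower_", b)]] <-
      if (total > 0) sum(pg$power[sel]) / total else 0
  }
  if (total <= 0) {
    out$peak_freq <- 0; out$median_freq <- 0
    out$total_energy <- 0; out$degenerate <- TRUE
  } else {
    out$peak_freq <- pg$freq[which.max(pg$power)]
    out$median_freq <- pg$freq[which(cumsum(pg$power) >= total / 2)[1]]
    out$total_energy <- total
    out$degenerate <- FALSE
  }
  out
}

#' Petrosian fractal dimension
#'
#' `PFD = log10(N) / (log10(N) + log10(N / (N + 0.4 * Nd)))` where `Nd`
#' counts sign changes in the first difference of the series. A constant
#' series has `Nd = 0` and PFD exactly 1.
#'
#' @param series Numeric vector, length >= 3.
#' @return PFD scalar.
#' @export
petrosian_fd <- function(series) {
  n <- length(series)
  stopifnot(n >= 3)
  d <- diff(series)
  s <- sign(d)
  s <- s[s != 0]
  nd <- if (length(s) > 1) sum(s[-1] != s[-length(s)]) else 0
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' SVD entropy of a delay embedding
#'
#' Builds the delay-embedding matrix (rows are length-`embed_dim` lagged
#' windows at spacing `delay`), takes its singular values, normalizes them
#' to sum 1, and returns the Shannon entropy `-sum(s * log2(s))` over the
#' nonzero normalized values. An all-zero series returns 0 (degenerate).
#'
#' @param series Numeric vector, longer than `embed_dim * delay`.
#' @param embed_dim Embedding dimension (default 20).
#' @param delay Lag between embedding coordinates (default 1).
#' @return Entropy in bits, at most `log2(embed_dim)`.
#' @export
svd_entropy <- function(series, embed_dim = 20L, delay = 1L) {
  stopifnot(length(series) > embed_dim * delay)
  series <- series - mean(series)      # offset must not affect complexity
  idx0 <- seq(0, by = delay, length.out = embed_dim)
  n_rows <- length(series) - (embed_dim - 1) * delay
  emb <- vapply(idx0, function(k) series[(1 + k):(n_rows + k)],
                numeric(n_rows))
  g <- crossprod(emb)                      # embed_dim x embed_dim Gram matrix
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  sv <- sqrt(ev)
  tot <- sum(sv)
  if (tot <= 0) return(0)
  p <- sv / tot
  p <- p[p > 1e-15]
  -sum(p * log2(p))
}

#' Pearson correlations between all montage channel pairs
#'
#' One value per unordered channel pair (45 for the standard 10-channel
#' montage), ordered column-wise over the upper triangle. A pair involving a
#' constant channel yields 0 and raises the degenerate flag.
#'
#' @param x Channels-by-samples matrix (one crop).
#' @return List with `values` (named vector) and `degenerate` flag.
#' @export
cross_channel_correlation <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  sds <- apply(x, 1, stats::sd)
  degenerate <- any(sds < 1e-12)
  xs <- x
  xs[sds < 1e-12, ] <- 0
  sds[sds < 1e-12] <- 1
  cm <- suppressWarnings(stats::cor(t(xs)))  # flat rows handled below
  cm[!is.finite(cm)] <- 0
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("ch", seq_len(nrow(x)))
  pairs <- utils::combn(nrow(x), 2)
  vals <- cm[t(pairs)]
  names(vals) <- paste0(labs[pairs[1, ]], "__", labs[pairs[2, ]])
  list(values = vals, degenerate = degenerate)
}

#' Temporal second-half/first-half signal-property ratio
#'
#' Splits each channel of a crop into two equal halves and returns
#' `property(second half) / (property(first half) + 1e-12)`. A window that
#' straddles the end of suppression has rising amplitude, so the ratio
#' exceeds 1.
#'
#' @param x Channels-by-samples matrix (one crop).
#' @param rate_hz Sampling rate (needed for `band_power`).
#' @param property One of `"rms"`, `"band_power"` (delta-band power),
#'   `"line_length"` (sum of absolute first differences).
#' @param band Hz interval for `band_power` (default delta).
#' @return Numeric vector, one ratio per channel.
#' @export
temporal_ratio <- function(x, rate_hz,
                           property = c("rms", "band_power", "line_length"),
                           band = c(0.5, 4)) {
  property <- match.arg(property)
  stopifnot(is.matrix(x), ncol(x) >= 4)
  half <- floor(ncol(x) / 2)
  prop <- switch(property,
    rms = function(v) sqrt(mean(v^2)),
    line_length = function(v) sum(abs(diff(v))),
    band_power = function(v) {
      pg <- periodogram(v, rate_hz)
      sum(pg$power[pg$freq >= band[1] & pg$freq <= min(band[2], rate_hz / 2)])
    })
  apply(x, 1, function(v)
    prop(v[(half + 1):(2 * half)]) / (prop(v[seq_len(half)]) + 1e-12))
}

#' Feature-bank configuration
#'
#' @param families Character vector choosing feature families among
#'   `"moments"`, `"spectral"`, `"petrosian"`, `"svd_entropy"`,
#'   `"correlation"`, `"temporal_ratio"`. Default: all.
#' @param bands Band set for spectral features.
#' @param embed_dim,delay SVD-entropy embedding parameters.
#' @return List of class `pges_feature_config`.
#' @export
feature_config <- function(families = c("moments", "spectral", "petrosian",
                                        "svd_entropy", "correlation",
                                        "temporal_ratio"),
                           bands = eeg_bands(), embed_dim = 20L, delay = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  structure(list(families = families, bands = bands,
                 embed_dim = embed_dim, delay = delay),
            class = "pges_feature_config")
}

# feature vector for one crop matrix; stable names and ordering
crop_features <- function(x, rate_hz, config = feature_config()) {
  x <- x - rowMeans(x)                 # EEG is AC-coupled: drop DC offsets
  out <- numeric(0)
  degen <- FALSE
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("ch", seq_len(nrow(x)))
  fam <- config$families
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    ch <- labs[i]
    if ("moments" %in% fam) {
      mf <- moment_features(v)
      degen <- degen || mf$degenerate
      out <- c(out, stats::setNames(
        c(mf$variance, mf$skewness, mf$kurtosis),
        paste0(ch, ".", c("variance", "skewness", "kurtosis"))))
    }
    if ("spectral" %in% fam) {
      sf <- spectral_features(v, rate_hz, config$bands)
      degen <- degen || sf$degenerate
      keep <- setdiff(names(sf), "degenerate")
      out <- c(out, stats::setNames(unlist(sf[keep]), paste0(ch, ".", keep)))
    }
    if ("petrosian" %in% fam)
      out <- c(out, stats::setNames(petrosian_fd(v), paste0(ch, ".pfd")))
    if ("svd_entropy" %in% fam)
      out <- c(out, stats::setNames(
        svd_entropy(v, config$embed_dim, config$delay),
        paste0(ch, ".svd_entropy")))
    if ("temporal_ratio" %in% fam)
      out <- c(out, stats::setNames(
        c(temporal_ratio(x[i, , drop = FALSE], rate_hz, "rms"),
          temporal_ratio(x[i, , drop = FALSE], rate_hz, "band_power"),
          temporal_ratio(x[i, , drop = FALSE], rate_hz, "line_length")),
        paste0(ch, ".ratio_", c("rms", "band_power", "line_length"))))
  }
  if ("correlation" %in% fam) {
    cc <- cross_channel_correlation(x)
    degen <- degen || cc$degenerate
    out <- c(out, stats::setNames(cc$values, paste0("cor.", names(cc$values))))
  }
  out <- c(out, degenerate_flag = as.numeric(degen))
  out[!is.finite(out)] <- 0
  out
}

#' Extract the feature matrix of a crop set
#'
#' Applies the configured feature bank to every crop. Deterministic: the
#' same crops give the same matrix regardless of order, and degenerate
#' (flat) inputs produce flagged sentinel values, never non-finite entries.
#'
#' @param crops A `pges_crops` object.
#' @param config A [feature_config()].
#' @return Numeric matrix, one row per crop, with stable column names.
#' @export
crop_feature_matrix <- function(crops, config = feature_config()) {
  stopifnot(inherits(crops, "pges_crops"))
  n <- dim(crops$data)[3]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x <- crops$data[, , i, drop = FALSE]
    dim(x) <- dim(crops$data)[1:2]
    rownames(x) <- crops$montage_labels
    rows[[i]] <- crop_features(x, crops$sampling_rate_hz, config)
  }
  do.call(rbind, rows)
}
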