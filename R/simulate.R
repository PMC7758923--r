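# Synthetic post-GTCS EEG: a low-amplitude suppression phase followed, at a
# known transition time, by intermittent delta-band slow-wave bursts, with
# optional eye-movement / breathing / muscle artifacts.

butter_filt <- function(x, w, type) {
  bf <- signal::butter(4, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

#' Configuration for the postictal EEG simulator
#'
#' @param duration_s Recording length in seconds (default 300, i.e. the
#'   5-minute post-seizure window reviewed clinically).
#' @param sampling_rate_hz Either a single rate or a vector of candidate
#'   acquisition rates from which cohort simulation samples (default
#'   `c(150, 200, 256)`, the clinical range).
#' @param suppression_rms_uv RMS amplitude of the suppressed background, in
#'   microvolts (default 3; PGES is near-flat).
#' @param slow_rms_uv RMS amplitude of slow-wave bursts (default 30); must
#'   exceed `suppression_rms_uv`.
#' @param slow_band_hz Two-element band of the slow activity in Hz (default
#'   delta, 0.5-4).
#' @param transition_s True end-of-suppression time in seconds, or `NULL` to
#'   sample it uniformly from `(20, duration_s - 30)` per recording.
#' @param intermittency_duty Long-run fraction of post-transition time spent
#'   inside slow-wave bursts (default 0.6); bursts alternate with quiet gaps
#'   as a two-state renewal process with exponential dwell times.
#' @param burst_mean_s Mean burst dwell time in seconds (default 3).
#' @param eye_uv,breathing_uv,muscle_uv Artifact amplitude scales in
#'   microvolts: slow (<1 Hz) frontal transients, a global ~0.3 Hz
#'   oscillation, and broadband >20 Hz temporal-channel bursts. All default
#'   to 0 (artifact-free).
#' @return A list of class `pges_sim_config`.
#' @export
sim_config <- function(duration_s = 300, sampling_rate_hz = c(150, 200, 256),
                       suppression_rms_uv = 3, slow_rms_uv = 30,
                       slow_band_hz = c(0.5, 4), transition_s = NULL,
                       intermittency_duty = 0.6, burst_mean_s = 3,
                       eye_uv = 0, breathing_uv = 0, muscle_uv = 0) {
  stopifnot(duration_s > 0, all(sampling_rate_hz > 0),
            suppression_rms_uv > 0, length(slow_band_hz) == 2,
            slow_band_hz[1] > 0, slow_band_hz[2] > slow_band_hz[1],
            intermittency_duty > 0, intermittency_duty <= 1,
            burst_mean_s > 0,
            eye_uv >= 0, breathing_uv >= 0, muscle_uv >= 0)
  if (slow_rms_uv <= suppression_rms_uv)
    stop("slow_rms_uv must exceed suppression_rms_uv")
  if (is.null(transition_s)) {
    if (duration_s <= 50)
      stop("sampled transitions need duration_s > 50 (drawn from ",
           "(20, duration_s - 30)); give transition_s explicitly for ",
           "shorter recordings")
  } else if (transition_s <= 0 || transition_s >= duration_s) {
    stop("transition_s must lie strictly inside (0, duration_s)")
  }
  structure(list(duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 suppression_rms_uv = suppression_rms_uv,
                 slow_rms_uv = slow_rms_uv, slow_band_hz = slow_band_hz,
                 transition_s = transition_s,
                 intermittency_duty = intermittency_duty,
                 burst_mean_s = burst_mean_s,
                 eye_uv = eye_uv, breathing_uv = breathing_uv,
                 muscle_uv = muscle_uv),
            class = "pges_sim_config")
}

# alternating burst/quiet renewal indicator on a sample grid
burst_envelope <- function(n, fs, duty, burst_mean_s) {
  quiet_mean_s <- burst_mean_s * (1 - duty) / duty
  env <- numeric(n)
  pos <- 0
  # the annotated transition is the onset of the FIRST slow-wave burst, so
  # the renewal process always opens in the burst state
  in_burst <- TRUE
  ramp_n <- max(2L, round(0.25 * fs))
  ramp <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  while (pos < n) {
    mean_s <- if (in_burst) burst_mean_s else quiet_mean_s
    len <- max(1L, round(stats::rexp(1, 1 / mean_s) * fs))
    seg <- (pos + 1):min(n, pos + len)
    if (in_burst) {
      e <- rep(1, length(seg))
      m <- min(ramp_n, length(seg))
      e[seq_len(m)] <- ramp[seq_len(m)]
      e[length(seg) - seq_len(m) + 1] <-
        pmin(e[length(seg) - seq_len(m) + 1], ramp[seq_len(m)])
      env[seg] <- e
    }
    pos <- pos + len
    in_burst <- !in_burst
  }
  if (duty >= 1) env[] <- 1
  env
}

#' Simulate one annotated postictal recording
#'
#' Generates a 13-electrode scalp recording that starts inside generalized
#' EEG suppression (band-limited low-amplitude noise) and, from the
#' configured transition time on, superposes intermittent bursts of
#' band-limited slow-wave activity, independently drawn per electrode so
#' that bipolar derivations retain the slow activity. Artifacts are added on
#' physiologically plausible channels: eye movements on Fp1/Fp2/F7/F8,
#' breathing globally, muscle bursts on F7/F8/T7/T8. Fully reproducible from
#' the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param recording_id Identifier for the generated recording.
#' @return List with elements `recording` (an [eeg_recording()] carrying the
#'   true `pges_end_s`) and `truth` (list with `recording_id`, `pges_end_s`,
#'   `config`).
#' @export
simulate_recording <- function(cfg, seed, recording_id = "sim") {
  stopifnot(inherits(cfg, "pges_sim_config"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  fs <- if (length(cfg$sampling_rate_hz) > 1)
    sample(cfg$sampling_rate_hz, 1) else cfg$sampling_rate_hz
  n <- round(cfg$duration_s * fs)
  transition <- if (is.null(cfg$transition_s))
    stats::runif(1, 20, cfg$duration_s - 30) else cfg$transition_s
  electrodes <- pges_electrodes()
  nch <- length(electrodes)
  t_idx <- seq_len(n)
  post <- t_idx > round(transition * fs)
  nyq <- fs / 2

  data <- matrix(0, nch, n)
  for (i in seq_len(nch)) {
    bg <- butter_filt(stats::rnorm(n), min(30, 0.9 * nyq) / nyq, "low")
    data[i, ] <- bg / stats::sd(bg) * cfg$suppression_rms_uv
  }

  if (any(post)) {
    env <- numeric(n)
    env[post] <- burst_envelope(sum(post), fs, cfg$intermittency_duty,
                                cfg$burst_mean_s)
    w <- cfg$slow_band_hz / nyq
    for (i in seq_len(nch)) {
      slow <- butter_filt(stats::rnorm(n), pmin(w, 0.99), "pass")
      slow <- slow / stats::sd(slow) * cfg$slow_rms_uv
      data[i, ] <- data[i, ] + slow * env
    }
  }

  if (cfg$breathing_uv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    breath <- sin(2 * pi * 0.3 * t_idx / fs + phase)
    gains <- stats::runif(nch, 0.5, 1.5)
    data <- data + outer(gains, breath) * cfg$breathing_uv
  }
  if (cfg$eye_uv > 0) {
    rows <- match(c("Fp1", "Fp2", "F7", "F8"), electrodes)
    n_ev <- stats::rpois(1, 0.08 * cfg$duration_s)
    for (ev in seq_len(n_ev)) {
      at <- stats::runif(1, 0, cfg$duration_s)
      width <- stats::runif(1, 0.3, 0.8)
      pulse <- exp(-((t_idx / fs - at)^2) / (2 * width^2))
      pol <- sample(c(-1, 1), 1)
      for (r in rows)
        data[r, ] <- data[r, ] + pol * stats::runif(1, 0.6, 1.4) *
          cfg$eye_uv * pulse
    }
  }
  if (cfg$muscle_uv > 0) {
    rows <- match(c("F7", "F8", "T7", "T8"), electrodes)
    n_ev <- stats::rpois(1, 0.05 * cfg$duration_s)
    hi <- min(20, 0.8 * nyq)
    for (ev in seq_len(n_ev)) {
      at <- stats::runif(1, 0, cfg$duration_s)
      len <- stats::runif(1, 0.5, 2)
      seg <- which(t_idx / fs >= at & t_idx / fs < at + len)
      if (length(seg) < 10) next
      burst <- butter_filt(stats::rnorm(length(seg) + 2 * fs), hi / nyq,
                           "high")[fs + seq_along(seg)]
      burst <- burst / stats::sd(burst) * cfg$muscle_uv
      r <- sample(rows, 1)
      data[r, seg] <- data[r, seg] + burst
    }
  }

  rec <- eeg_recording(recording_id, data, electrodes, fs,
                       pges_end_s = transition)
  list(recording = rec,
       truth = list(recording_id = recording_id, pges_end_s = transition,
                    config = cfg))
}

#' Simulate an annotated cohort of postictal recordings
#'
#' Per-recording seeds are derived deterministically from the cohort seed,
#' so the cohort is reproducible as a whole and each recording is
#' individually reproducible from the manifest.
#'
#' @param n Number of recordings.
#' @param cfg Base [sim_config()]; transition times (and the acquisition
#'   rate, when a vector of candidates is given) are sampled per recording.
#' @param seed Cohort seed.
#' @param out_dir Optional directory: when given, each recording is written
#'   there (EDF by default) together with `manifest.csv`.
#' @param format `"edf"` or `"simple"` when writing.
#' @return List with `recordings` (list of `simulate_recording()` results)
#'   and `manifest` (data frame with recording_id, seed, pges_end_s,
#'   sampling_rate_hz).
#' @export
simulate_cohort <- function(n, cfg = sim_config(), seed = 1, out_dir = NULL,
                            format = c("edf", "simple")) {
  if (n < 1) stop("n must be >= 1")
  format <- match.arg(format)
  seeds <- (as.numeric(seed) * 10007 + 17 * seq_len(n)) %% 2147483647
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("sim%03d", i)
    recs[[i]] <- simulate_recording(cfg, seeds[i], recording_id = id)
  }
  manifest <- data.frame(
    recording_id = vapply(recs, function(r) r$recording$recording_id, ""),
    seed = seeds,
    pges_end_s = vapply(recs, function(r) r$truth$pges_end_s, 0),
    sampling_rate_hz = vapply(recs, function(r) r$recording$sampling_rate_hz, 0),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in recs) {
      if (format == "edf")
        write_edf(r$recording,
                  file.path(out_dir, paste0(r$recording$recording_id, ".edf")))
      else
        write_simple_eeg(r$recording,
                         file.path(out_dir, r$recording$recording_id))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}
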