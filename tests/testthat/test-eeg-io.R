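test_that("simple-format write/read round-trips exactly", {
  rec <- eeg_recording("toy", matrix(c(1.5, -2, 3, 0.25, 7, -1), 2, 3,
                                     byrow = TRUE),
                       c("Fz", "Cz"), 2, pges_end_s = 1)
  expect_equal(rec$duration_s, 1.5)
  d <- withr::local_tempdir()
  write_simple_eeg(rec, file.path(d, "toy"))
  back <- read_simple_eeg(file.path(d, "toy"))
  expect_equal(back$data, rec$data)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$sampling_rate_hz, 2)
  expect_equal(back$pges_end_s, 1)
})

test_that("simple-format reader validates shape and annotation", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "bad"))
  utils::write.table(matrix(1:8, 2, 4), file.path(d, "bad", "signals.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(recording_id = "bad",
                            channel_labels = c("a", "b", "c"),
                            sampling_rate_hz = 2),
                       file.path(d, "bad", "meta.json"), auto_unbox = TRUE)
  expect_error(read_simple_eeg(file.path(d, "bad")), "shape mismatch")
  # toy 2 channel, 4 samples at 2 Hz -> 2 s duration
  jsonlite::write_json(list(recording_id = "bad",
                            channel_labels = c("a", "b"),
                            sampling_rate_hz = 2),
                       file.path(d, "bad", "meta.json"), auto_unbox = TRUE)
  expect_equal(read_simple_eeg(file.path(d, "bad"))$duration_s, 2)
  # out-of-range annotation rejected
  jsonlite::write_json(list(recording_id = "bad",
                            channel_labels = c("a", "b"),
                            sampling_rate_hz = 2, pges_end_s = 500),
                       file.path(d, "bad", "meta.json"), auto_unbox = TRUE)
  expect_error(read_simple_eeg(file.path(d, "bad")), "pges_end_s")
})

test_that("EDF write/read round-trips within calibration quantization", {
  cfg <- sim_config(duration_s = 10, sampling_rate_hz = 200,
                    transition_s = 5)
  rec <- simulate_recording(cfg, 1, "rt")$recording
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, pges_end_s = 5)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$sampling_rate_hz, 200)
  expect_equal(back$duration_s, 10)
  expect_equal(back$pges_end_s, 5)
  qstep <- max(apply(rec$data, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(back$data - rec$data)), 1.5 * qstep)
})

test_that("EDF reader subsets channels and flags missing electrodes", {
  cfg <- sim_config(duration_s = 5, sampling_rate_hz = 150, transition_s = 2)
  rec <- simulate_recording(cfg, 2, "sub")$recording
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_warning(back <- read_edf(path, channels = c("Fz", "Cz")),
                 "ignoring")
  expect_equal(back$channel_labels, c("Fz", "Cz"))
  expect_error(suppressWarnings(read_edf(path, channels = "Oz")), "absent")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "no such file")
})

test_that("simulated cohort EDFs reload as 13-channel recordings", {
  d <- withr::local_tempdir()
  cfg <- sim_config(duration_s = 60, sampling_rate_hz = 200)
  coh <- simulate_cohort(2, cfg, seed = 4, out_dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- read_edf(file.path(d, "sim001.edf"))
  expect_equal(length(back$channel_labels), 13)
  expect_equal(back$duration_s, 60)
})

test_that("bipolar montage is the anode-minus-cathode difference", {
  set.seed(1)
  x <- matrix(rnorm(13 * 50), 13, 50)
  rec <- eeg_recording("m", x, pges_electrodes(), 10)
  m <- to_bipolar_montage(rec)
  expect_equal(length(m$montage_labels), 10)
  expect_equal(m$montage_labels[1], "Fp1-F7")
  expect_equal(m$data["Fp1-F7", ],
               rec$data["Fp1", ] - rec$data["F7", ], ignore_attr = TRUE)
  # antisymmetry under anode/cathode swap, and x - x = 0
  sw <- to_bipolar_montage(rec, data.frame(anode = "F7", cathode = "Fp1"))
  expect_equal(sw$data[1, ], -m$data["Fp1-F7", ], ignore_attr = TRUE)
  rec$data["Fp1", ] <- rec$data["F7", ]
  expect_true(all(to_bipolar_montage(rec)$data["Fp1-F7", ] == 0))
})

test_that("montage rejects unknown electrodes and duplicate pairs", {
  rec <- eeg_recording("m", matrix(0, 2, 10), c("Fz", "Cz"), 10)
  expect_error(to_bipolar_montage(rec), "not present")
  expect_error(
    to_bipolar_montage(rec, data.frame(anode = c("Fz", "Fz"),
                                       cathode = c("Cz", "Cz"))),
    "duplicate")
  expect_error(
    to_bipolar_montage(rec, data.frame(anode = "Fz", cathode = "Fz")),
    "identical")
})

test_that("resampling fixes the sample count and preserves content", {
  # constants are fixed points: 150 -> 200 Hz
  rec <- eeg_recording("c", matrix(2.5, 13, 1500), pges_electrodes(), 150,
                       pges_end_s = 4)
  m <- resample_montage(to_bipolar_montage(rec), 200)
  expect_equal(ncol(m$data), 2000)
  expect_equal(m$sampling_rate_hz, 200)
  expect_equal(m$duration_s, 10)
  expect_equal(m$pges_end_s, 4)
  expect_true(all(abs(m$data) < 1e-9))  # montage of a constant is 0

  # a 5 Hz sine at 256 Hz keeps its dominant frequency at 200 Hz
  fs <- 256; t <- (0:(10 * fs - 1)) / fs
  x <- matrix(0, 13, length(t), dimnames = list(pges_electrodes(), NULL))
  x["Fp1", ] <- sin(2 * pi * 5 * t)
  rec <- eeg_recording("s", x, pges_electrodes(), fs)
  m <- resample_montage(to_bipolar_montage(rec), 200)
  y <- m$data["Fp1-F7", ]
  sp <- Mod(stats::fft(y))[2:(length(y) / 2)]
  f_peak <- (which.max(sp)) * 200 / length(y)
  expect_lt(abs(f_peak - 5), 200 / length(y) + 1e-9)  # within one bin
  # a 300 s recording lands on exactly 60000 samples
  expect_equal(round(300 * 200), 60000)
})

test_that("Hann denoising preserves means and shrinks white noise", {
  set.seed(2)
  x <- matrix(rnorm(13 * 4000), 13, 4000)
  rec <- eeg_recording("h", x, pges_electrodes(), 200)
  m <- to_bipolar_montage(rec)
  sm <- hann_denoise(m, 11)
  expect_equal(dim(sm$data), dim(m$data))
  expect_equal(rowMeans(sm$data), rowMeans(m$data), tolerance = 1e-9)
  expect_true(all(apply(sm$data, 1, var) < apply(m$data, 1, var)))
  # constants unchanged
  cm <- m; cm$data[] <- 3.25
  expect_equal(hann_denoise(cm, 11)$data, cm$data, tolerance = 1e-12)
  expect_error(hann_denoise(m, 1), "odd")
  expect_error(hann_denoise(m, 10), "odd")
})
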