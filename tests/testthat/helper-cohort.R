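# Shared fixtures, built once per test run and memoized.
#
# The "easy" cohort is the package's standard recovery benchmark: 40
# artifact-free recordings (3 uV suppression, 30 uV slow waves), 120 s each
# at mixed acquisition rates, transitions sampled inside (20, 90) s,
# recording-level 80/20 split. Dataset crops use a 1 s stride and traces a
# 0.5 s stride to keep the run desk-sized; window and latency stay at the
# 10 s operating point.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

easy_sim_config <- function(slow_rms_uv = 30, duration_s = 120)
  sim_config(duration_s = duration_s,
             sampling_rate_hz = c(150, 200, 256),
             suppression_rms_uv = 3, slow_rms_uv = slow_rms_uv)

prep_cohort <- function(n, cfg, seed, stride_s = 1) {
  coh <- simulate_cohort(n, cfg, seed = seed)
  mrecs <- lapply(coh$recordings, function(r)
    resample_montage(to_bipolar_montage(r$recording), 200))
  names(mrecs) <- coh$manifest$recording_id
  sp <- split_recordings(coh$manifest$recording_id, 0.8, seed = seed)
  crops <- lapply(mrecs, enumerate_crops,
                  spec = crop_spec(10, stride_s, 10))
  list(manifest = coh$manifest, mrecs = mrecs, split = sp,
       train = bind_crops(crops[sp$train]),
       test = bind_crops(crops[sp$test]))
}

easy_cohort <- function()
  memo("easy_cohort", function() prep_cohort(40, easy_sim_config(), seed = 11))

easy_rf <- function() memo("easy_rf", function()
  pges_detector(easy_cohort()$train, "random_forest", seed = 11))

easy_rf_test_probs <- function() memo("easy_rf_probs", function()
  predict(easy_rf(), easy_cohort()$test))

easy_cnn <- function() memo("easy_cnn", function()
  pges_detector(easy_cohort()$train, "cnn",
                arch = cnn_config(temporal_filters = 4, spatial_filters = 8),
                train_cfg = cnn_train_config(epochs = 5, seed = 11),
                seed = 11))

easy_eval <- function() memo("easy_eval", function()
  evaluate_cohort(easy_rf(), easy_cohort()$mrecs[easy_cohort()$split$test],
                  crop_spec(10, 0.5, 10)))

# small montaged recording for fast unit tests
toy_montaged <- function(seed = 5, duration_s = 40, transition_s = 22,
                         fs = 200) {
  cfg <- sim_config(duration_s = duration_s, sampling_rate_hz = fs,
                    suppression_rms_uv = 3, slow_rms_uv = 30,
                    transition_s = transition_s)
  to_bipolar_montage(simulate_recording(cfg, seed)$recording)
}
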