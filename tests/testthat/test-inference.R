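flat_mrec <- function(duration_s = 60, fs = 20, pges_end_s = 30, nch = 3) {
  set.seed(14)
  pgesdetect:::new_montaged("flat", paste0("m", seq_len(nch)),
                            matrix(rnorm(nch * duration_s * fs), nch),
                            fs, pges_end_s)
}

test_that("probability traces sit on the stride grid of window ends", {
  mrec <- flat_mrec(duration_s = 300)
  det <- stub_detector(function(x, end) 0.2, spec = crop_spec(10, 0.1, 10),
                       fs = 20)
  tr <- probability_trace(det, mrec)
  expect_equal(length(tr$times_s), floor((300 - 10) / 0.1) + 1)
  expect_equal(length(tr$times_s), 2901)
  expect_equal(tr$times_s[1], 10)
  expect_equal(unique(round(diff(tr$times_s), 9)), 0.1)
  expect_true(all(tr$probs == 0.2))
  short <- flat_mrec(duration_s = 5)
  expect_error(probability_trace(det, short), "shorter than one window")
})

test_that("trace values are causal under truncation of the future", {
  mrec <- flat_mrec(duration_s = 60)
  # probability depends on the actual samples in the window
  det <- stub_detector(function(x, end) 1 / (1 + exp(-mean(x))),
                       spec = crop_spec(10, 0.5, 10), fs = 20)
  full <- probability_trace(det, mrec)
  cut_s <- 40
  trunc <- mrec
  trunc$data <- mrec$data[, 1:(cut_s * 20), drop = FALSE]
  trunc$duration_s <- cut_s
  part <- probability_trace(det, trunc)
  keep <- full$times_s <= cut_s + 1e-9
  expect_equal(full$probs[keep], part$probs)
  # and modifying samples after t never changes values at times <= t
  mod <- mrec
  mod$data[, (cut_s * 20 + 1):ncol(mod$data)] <- 999
  tr_mod <- probability_trace(det, mod)
  expect_identical(tr_mod$probs[keep], full$probs[keep])
})

test_that("onset calling follows the threshold + k-consecutive rule", {
  mk_trace <- function(p) structure(
    list(recording_id = "t", times_s = seq(10, by = 0.1,
                                           length.out = length(p)),
         probs = p, spec = crop_spec(10, 0.1, 10), pges_end_s = NULL),
    class = "pges_trace")
  # step trace: detection at the first grid point at/after the step
  tm <- seq(10, by = 0.1, length.out = 2000)
  p <- as.numeric(tm >= 120)
  d <- detect_onset(mk_trace(p), onset_rule(0.5, 1))
  expect_equal(d$detected_s, tm[which(tm >= 120)[1]])
  # sub-threshold trace never detects
  expect_true(is.na(detect_onset(mk_trace(rep(0.4, 100)),
                                 onset_rule(0.5, 3))$detected_s))
  # an isolated one-sample spike does not satisfy k = 3
  p2 <- rep(0, 500); p2[401] <- 1
  expect_true(is.na(detect_onset(mk_trace(p2), onset_rule(0.5, 3))$detected_s))
  p2[401:403] <- 1
  expect_equal(detect_onset(mk_trace(p2), onset_rule(0.5, 3))$detected_s,
               mk_trace(p2)$times_s[401])
  # raising the threshold never makes detection earlier
  set.seed(15)
  for (i in 1:20) {
    p3 <- stats::runif(300)
    lo <- detect_onset(mk_trace(p3), onset_rule(0.3, 3))$detected_s
    hi <- detect_onset(mk_trace(p3), onset_rule(0.7, 3))$detected_s
    if (!is.na(lo) && !is.na(hi)) expect_gte(hi, lo)
    if (is.na(lo)) expect_true(is.na(hi))
  }
})

test_that("crop_auc equals the Mann-Whitney pair enumeration", {
  expect_equal(crop_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(crop_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(crop_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(16)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(stats::runif(n), sample(c(1, 2, 8), 1))  # force some ties
    expect_identical(crop_auc(s, y), brute(s, y))
  }
  expect_error(crop_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("cohort evaluation scores oracle and useless detectors correctly", {
  mrecs <- lapply(1:3, function(i) flat_mrec(60, 20, pges_end_s = 20 + 5 * i))
  # oracle probability = true label, per recording
  evs <- lapply(mrecs, function(m) {
    o <- stub_detector(function(x, end) as.numeric(end >= m$pges_end_s),
                       spec = crop_spec(10, 0.5, 10), fs = 20)
    evaluate_cohort(o, list(m), rule = onset_rule(0.5, 3))
  })
  for (ev in evs) {
    expect_equal(ev$auc, 1)
    expect_equal(ev$detection_rate, 1)
    expect_equal(ev$false_alarm_rate, 0)
    expect_equal(ev$median_latency_s, 0)
  }
  # constant 0.5 detects immediately (>= threshold) -> false alarm
  const <- stub_detector(function(x, end) 0.5, spec = crop_spec(10, 0.5, 10),
                         fs = 20)
  ev <- evaluate_cohort(const, mrecs, rule = onset_rule(0.5, 3))
  expect_equal(ev$auc, 0.5)
  expect_equal(ev$detection_rate, 0)
  expect_equal(ev$false_alarm_rate, 1)
  # constant sub-threshold never detects: absent detection is incorrect
  meek <- stub_detector(function(x, end) 0.2, spec = crop_spec(10, 0.5, 10),
                        fs = 20)
  ev2 <- evaluate_cohort(meek, mrecs, rule = onset_rule(0.5, 3))
  expect_equal(ev2$detection_rate, 0)
  expect_equal(ev2$false_alarm_rate, 0)
  expect_error(evaluate_cohort(meek, list(flat_mrec(60, 20, NULL))),
               "no annotated")
})

test_that("evaluation reports round-trip to disk", {
  mrecs <- lapply(1:2, function(i) flat_mrec(40, 20, pges_end_s = 20))
  o <- stub_detector(function(x, end) as.numeric(end >= 20),
                     spec = crop_spec(10, 0.5, 10), fs = 20)
  ev <- evaluate_cohort(o, mrecs)
  d <- withr::local_tempdir()
  write_report(ev, d)
  agg <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(agg$auc, 1)
  per <- utils::read.csv(file.path(d, "per_recording.csv"))
  expect_equal(nrow(per), 2)
  expect_true(all(per$correct))
})

test_that("trace plots are written and omit what is absent", {
  mrec <- flat_mrec(60, 20, pges_end_s = 30)
  det <- stub_detector(function(x, end) as.numeric(end >= 30),
                       spec = crop_spec(10, 0.5, 10), fs = 20)
  tr <- probability_trace(det, mrec)
  f <- withr::local_tempfile(fileext = ".png")
  export_trace_plot(mrec, tr, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # no truth annotation and no detection: still renders
  mrec2 <- mrec; mrec2$pges_end_s <- NULL
  tr2 <- probability_trace(stub_detector(function(x, end) 0.1,
                                         spec = crop_spec(10, 0.5, 10),
                                         fs = 20), mrec2)
  f2 <- withr::local_tempfile(fileext = ".png")
  export_trace_plot(mrec2, tr2, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
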