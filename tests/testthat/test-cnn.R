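# small architecture used throughout: fast to build and train
tiny_arch <- function(dropout = 0)
  cnn_config(n_channels = 3, n_samples = 200, temporal_filters = 2,
             temporal_kernel_len = 9, spatial_filters = 3,
             depthwise_multiplier = 2, depthwise_kernel_len = 5,
             pointwise_filters = 4, pool1 = 4, pool2 = 4,
             dropout_rate = dropout)

tiny_crops <- function(n = 24, seed = 1, fs = 20) {
  set.seed(seed)
  data <- array(rnorm(3 * 200 * n), dim = c(3, 200, n))
  label <- rep(0:1, length.out = n)
  # positives get a visible low-frequency component
  t <- (0:199) / fs
  for (i in which(label == 1))
    data[, , i] <- data[, , i] + 6 * sin(2 * pi * 1.5 * t)
  structure(list(data = data,
                 index = data.frame(recording_id = sprintf("r%02d", seq_len(n)),
                                    start_s = 0, end_s = 10, label = label),
                 spec = crop_spec(10, 1, 10), sampling_rate_hz = fs,
                 montage_labels = paste0("m", 1:3)),
            class = "pges_crops")
}

test_that("parameter count equals the hand-derived layer-shape arithmetic", {
  # derived before building: conv kernels + biases, BN scale/shift, dense
  count_by_hand <- function(C, T, F1, k1, F2, D, k2, F3, p1, p2) {
    t1 <- T - k1 + 1; t2 <- t1 %/% p1; t3 <- t2 - k2 + 1; t4 <- t3 %/% p2
    (F1 * k1 + F1) + (F2 * F1 * C + F2) + 2 * F2 +
      (F2 * D * k2 + F2 * D) + (F3 * F2 * D + F3) + 2 * F3 +
      (F3 * t4 + 1)
  }
  expect_equal(cnn_n_params(tiny_arch()),
               count_by_hand(3, 200, 2, 9, 3, 2, 5, 4, 4, 4))
  default <- cnn_config()
  expect_equal(cnn_n_params(default),
               count_by_hand(10, 2000, 8, 18, 101, 2, 16, 16, 8, 8))
})

test_that("architecture validation rejects impossible shapes", {
  expect_error(cnn_config(n_samples = 100, temporal_kernel_len = 5000),
               "longer than the input")
  expect_error(cnn_config(dropout_rate = 1), "dropout")
  expect_error(cnn_config(temporal_filters = 0), "counts")
})

test_that("training is seeded-deterministic and predictions are sane", {
  crops <- tiny_crops()
  tc <- cnn_train_config(epochs = 3, batch_size = 8, seed = 4)
  f1 <- pges_detector(crops, "cnn", arch = tiny_arch(0.25), train_cfg = tc,
                      validation = tiny_crops(12, seed = 2), seed = 4)
  f2 <- pges_detector(crops, "cnn", arch = tiny_arch(0.25), train_cfg = tc,
                      validation = tiny_crops(12, seed = 2), seed = 4)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  p <- predict(f1, crops)
  expect_length(p, 24)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated crop -> duplicated probability; batch size cannot matter
  dup <- pgesdetect:::subset_crops(crops, c(1, 1, 5))
  pd <- predict(f1, dup)
  expect_equal(pd[1], pd[2])
  expect_equal(pd[3], p[5], tolerance = 1e-12)
})

test_that("a single optimizer step decreases the batch loss", {
  arch <- tiny_arch(0)
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- array(rnorm(3 * 200 * 16), dim = c(3, 200, 16))
    y <- rep(0:1, each = 8)
    ll <- pgesdetect:::.cnn_step_loss(
      X, y, unclass(arch),
      list(learning_rate = 1e-3, seed = s, class_weights = c(1, 1)))
    if (ll[2] < ll[1]) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("training separable data makes progress and tracks history", {
  crops <- tiny_crops(32, seed = 6)
  val <- tiny_crops(16, seed = 7)
  fit <- pges_detector(crops, "cnn", arch = tiny_arch(0.1),
                       train_cfg = cnn_train_config(epochs = 8,
                                                    batch_size = 8, seed = 3),
                       validation = val, seed = 3)
  h <- fit$history
  expect_equal(nrow(h), 8)
  expect_gt(h$train_loss[1], min(h$train_loss))
  expect_gte(max(h$val_auc, na.rm = TRUE), 0.9)
  expect_equal(fit$best_epoch, which.max(h$val_auc))
  expect_null(coef(fit))
})

test_that("mismatched crop shapes and single-class data are rejected", {
  crops <- tiny_crops(10)
  bad_arch <- cnn_config(n_channels = 3, n_samples = 100,
                         temporal_kernel_len = 9, depthwise_kernel_len = 2,
                         pool1 = 4, pool2 = 4)
  expect_error(pges_detector(crops, "cnn", arch = bad_arch,
                             train_cfg = cnn_train_config(epochs = 1)),
               "shape")
  ones <- pgesdetect:::subset_crops(crops, which(crops$index$label == 1))
  expect_error(pges_detector(ones, "cnn", arch = tiny_arch(),
                             train_cfg = cnn_train_config(epochs = 1)),
               "single class")
})
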