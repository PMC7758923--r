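#' Architecture configuration for the compact EEG CNN
#'
#' The network stacks: a temporal convolution (kernel length 18 samples,
#' 90 ms at 200 Hz) shared across montages; a spatial convolution whose
#' filters span all montages; batch-norm / ReLU / average-pool / dropout; a
#' depthwise temporal convolution and a pointwise (1x1) convolution
#' aggregating spatio-temporal features; a second batch-norm / ReLU /
#' average-pool / dropout block; and a fully connected sigmoid output giving
#' the probability that the crop reaches the end of suppression.
#'
#' @param n_channels Montage channels in a crop (default 10).
#' @param n_samples Samples per crop (default 2000: a 10 s window at 200 Hz).
#' @param temporal_filters Number of temporal filters (default 8).
#' @param temporal_kernel_len Temporal kernel length in samples (default 18).
#' @param spatial_filters Number of spatial filters spanning all montages
#'   (default 101).
#' @param depthwise_multiplier Depthwise kernels per spatial map (default 2).
#' @param depthwise_kernel_len Depthwise kernel length in pooled samples
#'   (default 16).
#' @param pointwise_filters Pointwise (1x1) output maps (default 16).
#' @param pool1,pool2 Average-pooling factors after each conv block
#'   (default 8 and 8).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.25).
#' @return List of class `pges_cnn_config` including the derived map lengths
#'   (`t1` after the temporal conv, `t2`/`t3`/`t4` after pooling and the
#'   depthwise stage) and `n_flat`, the fully-connected input width.
#' @export
cnn_config <- function(n_channels = 10L, n_samples = 2000L,
                       temporal_filters = 8L, temporal_kernel_len = 18L,
                       spatial_filters = 101L, depthwise_multiplier = 2L,
                       depthwise_kernel_len = 16L, pointwise_filters = 16L,
                       pool1 = 8L, pool2 = 8L, dropout_rate = 0.25) {
  cfg <- list(n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              temporal_filters = as.integer(temporal_filters),
              temporal_kernel_len = as.integer(temporal_kernel_len),
              spatial_filters = as.integer(spatial_filters),
              depthwise_multiplier = as.integer(depthwise_multiplier),
              depthwise_kernel_len = as.integer(depthwise_kernel_len),
              pointwise_filters = as.integer(pointwise_filters),
              pool1 = as.integer(pool1), pool2 = as.integer(pool2),
              dropout_rate = as.numeric(dropout_rate))
  counts <- unlist(cfg[c("n_channels", "n_samples", "temporal_filters",
                         "temporal_kernel_len", "spatial_filters",
                         "depthwise_multiplier", "depthwise_kernel_len",
                         "pointwise_filters", "pool1", "pool2")])
  if (any(counts < 1)) stop("all architecture counts must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  cfg$t1 <- cfg$n_samples - cfg$temporal_kernel_len + 1L
  if (cfg$t1 < 1)
    stop("temporal kernel (", cfg$temporal_kernel_len,
         ") longer than the input window (", cfg$n_samples, " samples)")
  cfg$t2 <- cfg$t1 %/% cfg$pool1
  cfg$t3 <- cfg$t2 - cfg$depthwise_kernel_len + 1L
  if (cfg$t3 < 1)
    stop("depthwise kernel longer than the pooled feature map")
  cfg$t4 <- cfg$t3 %/% cfg$pool2
  if (cfg$t4 < 1) stop("second pooling leaves no samples")
  cfg$n_flat <- cfg$pointwise_filters * cfg$t4
  structure(cfg, class = "pges_cnn_config")
}

#' Training configuration for the CNN
#'
#' Binary cross-entropy loss minimized with Adam; optional inverse-frequency
#' class weighting counters the negative-heavy crop imbalance.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Crops per batch (default 64).
#' @param epochs Training epochs (default 30).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param class_balancing `"weighted"` (inverse-frequency weights in the
#'   loss, the default) or `"none"`.
#' @return List of class `pges_cnn_train_config`.
#' @export
cnn_train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                             epochs = 30L, seed = 1L,
                             class_balancing = c("weighted", "none")) {
  stopifnot(learning_rate > 0, batch_size >= 2, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed %% .Machine$integer.max),
                 class_balancing = match.arg(class_balancing)),
            class = "pges_cnn_train_config")
}

#' Number of trainable parameters of a CNN configuration
#'
#' Counts the entries of every trainable tensor of a freshly initialized
#' network (convolution kernels and biases, batch-norm scale/shift, and the
#' fully connected layer; batch-norm running statistics are not trainable).
#'
#' @param cfg A [cnn_config()].
#' @return Integer parameter count.
#' @export
cnn_n_params <- function(cfg) {
  stopifnot(inherits(cfg, "pges_cnn_config"))
  w <- .cnn_init(unclass(cfg), 1L)
  trainable <- setdiff(names(w), c("rm1", "rv1", "rm2", "rv2"))
  sum(vapply(w[trainable], length, 0L))
}

class_weights <- function(y, balancing) {
  if (balancing == "none") return(c(1, 1))
  n <- length(y); n1 <- sum(y); n0 <- n - n1
  if (n0 == 0 || n1 == 0) stop("training data contains a single class")
  c(n / (2 * n0), n / (2 * n1))
}

fit_cnn_detector <- function(crops, val_crops, arch, train_cfg) {
  y <- crops$index$label
  if (length(unique(y)) < 2) stop("training data contains a single class")
  if (dim(crops$data)[1] != arch$n_channels ||
      dim(crops$data)[2] != arch$n_samples)
    stop("crop shape ", dim(crops$data)[1], "x", dim(crops$data)[2],
         " does not match the architecture input shape ",
         arch$n_channels, "x", arch$n_samples)
  tc <- unclass(train_cfg)
  tc$class_weights <- class_weights(y, train_cfg$class_balancing)
  has_val <- !is.null(val_crops) && nrow(val_crops$index) > 0
  Xval <- if (has_val) val_crops$data else
    array(0, dim = c(arch$n_channels, arch$n_samples, 0))
  yval <- if (has_val) as.numeric(val_crops$index$label) else numeric(0)
  fit <- .cnn_fit(crops$data, as.numeric(y), Xval, yval,
                  unclass(arch), tc)
  list(params = fit$params,
       history = data.frame(epoch = seq_along(fit$train_loss),
                            train_loss = fit$train_loss,
                            val_auc = fit$val_auc),
       best_epoch = fit$best_epoch)
}
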