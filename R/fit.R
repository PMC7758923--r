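#' Fit a PGES end-of-suppression detector
#'
#' The single model-fitting entry point. Three detector families are
#' supported, all mapping a 10-montage crop to the probability that the crop
#' reaches the end of suppression:
#' \describe{
#'   \item{`random_forest`}{probability forest (via ranger) on the
#'     spectral/fractal/entropy feature bank of [crop_feature_matrix()].}
#'   \item{`gradient_boosted_trees`}{gradient boosted decision trees (via
#'     xgboost) on the same feature bank.}
#'   \item{`cnn`}{the compact EEGNet-style convolutional network of
#'     [cnn_config()], trained on raw crops with binary cross-entropy and
#'     Adam.}
#' }
#' Feature inputs are z-scored with means/sds estimated on the training
#' crops only. For the CNN, a recording-level validation split (no crop
#' leakage across recordings) monitors per-epoch AUC and the
#' best-validation weights are retained.
#'
#' @param crops Training crops from [enumerate_crops()]/[bind_crops()];
#'   must contain both classes.
#' @param method One of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"cnn"`.
#' @param feature_cfg [feature_config()] for the tree methods.
#' @param arch [cnn_config()] for the CNN; defaults to the crop dimensions.
#' @param train_cfg [cnn_train_config()] for the CNN.
#' @param validation Optional `pges_crops` used for CNN validation; by
#'   default a fraction of training recordings is held out.
#' @param validation_fraction Recording fraction held out for CNN
#'   validation when `validation` is NULL (default 0.2).
#' @param num_trees Trees for the random forest (default 300).
#' @param nrounds Boosting rounds for xgboost (default 150).
#' @param seed Integer seed (model fitting and validation split).
#' @return An object of class `pges_detector`.
#' @seealso [predict.pges_detector()], [probability_trace()],
#'   [evaluate_cohort()]
#' @export
pges_detector <- function(crops,
                          method = c("random_forest",
                                     "gradient_boosted_trees", "cnn"),
                          feature_cfg = feature_config(),
                          arch = NULL, train_cfg = NULL,
                          validation = NULL, validation_fraction = 0.2,
                          num_trees = 300L, nrounds = 150L, seed = 1L) {
  stopifnot(inherits(crops, "pges_crops"))
  method <- match.arg(method)
  y <- crops$index$label
  if (length(unique(y)) < 2)
    stop("training crops contain a single class; cannot fit a classifier")
  obj <- list(method = method, spec = crops$spec,
              sampling_rate_hz = crops$sampling_rate_hz,
              montage_labels = crops$montage_labels,
              n_train = nrow(crops$index),
              class_counts = table(factor(y, levels = 0:1)),
              seed = as.integer(seed))

  if (method == "cnn") {
    if (is.null(arch))
      arch <- cnn_config(n_channels = dim(crops$data)[1],
                         n_samples = dim(crops$data)[2])
    if (is.null(train_cfg)) train_cfg <- cnn_train_config(seed = seed)
    val <- validation
    if (is.null(val)) {
      ids <- unique(crops$index$recording_id)
      if (length(ids) >= 2) {
        sp <- split_recordings(ids, 1 - validation_fraction, seed = seed)
        keep <- crops$index$recording_id %in% sp$train
        if (any(!keep) && length(unique(y[keep])) == 2) {
          val <- subset_crops(crops, which(!keep))
          crops_fit <- subset_crops(crops, which(keep))
        } else crops_fit <- crops
      } else crops_fit <- crops
    } else crops_fit <- crops
    fit <- fit_cnn_detector(crops_fit, val, arch, train_cfg)
    obj$arch <- arch
    obj$train_cfg <- train_cfg
    obj$params <- fit$params
    obj$history <- fit$history
    obj$best_epoch <- fit$best_epoch
    obj$n_params <- cnn_n_params(arch)
  } else {
    X <- crop_feature_matrix(crops, feature_cfg)
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    Xs <- scale(X, center = ctr, scale = scl)
    obj$feature_cfg <- feature_cfg
    obj$center <- ctr
    obj$scale <- scl
    obj$feature_names <- colnames(X)
    if (method == "random_forest") {
      df <- as.data.frame(Xs)
      df$.label <- factor(y, levels = 0:1)
      obj$model <- ranger::ranger(
        dependent.variable.name = ".label", data = df,
        probability = TRUE, num.trees = num_trees,
        importance = "impurity", seed = seed, num.threads = 1)
      obj$importance <- sort(obj$model$variable.importance,
                             decreasing = TRUE)
    } else {
      dtrain <- xgboost::xgb.DMatrix(Xs, label = y)
      set.seed(seed)
      obj$model <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4,
                      eta = 0.1, nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = obj$model)
      obj$importance <- stats::setNames(imp$Gain, imp$Feature)
    }
  }
  class(obj) <- "pges_detector"
  obj
}

# take crops at the given indices (used for validation splitting)
subset_crops <- function(crops, idx) {
  structure(list(data = crops$data[, , idx, drop = FALSE],
                 index = crops$index[idx, , drop = FALSE],
                 spec = crops$spec,
                 sampling_rate_hz = crops$sampling_rate_hz,
                 montage_labels = crops$montage_labels),
            class = "pges_crops")
}

#' Predict end-of-suppression probabilities
#'
#' For a `pges_crops` input, returns one probability per crop (order
#' preserving). For an `eeg_montaged` recording, slides the detector along
#' the recording and returns the full [probability_trace()].
#'
#' @param object A fitted [pges_detector()].
#' @param newdata A `pges_crops` set or an `eeg_montaged` recording.
#' @param ... Passed to [probability_trace()] for recording input.
#' @return Numeric probability vector, or a `pges_trace` for recordings.
#' @export
predict.pges_detector <- function(object, newdata, ...) {
  if (inherits(newdata, "eeg_montaged"))
    return(probability_trace(object, newdata, ...))
  stopifnot(inherits(newdata, "pges_crops"))
  if (object$method == "cnn") {
    as.numeric(.cnn_predict(object$params, newdata$data,
                            unclass(object$arch)))
  } else {
    X <- crop_feature_matrix(newdata, object$feature_cfg)
    X <- X[, object$feature_names, drop = FALSE]
    Xs <- scale(X, center = object$center, scale = object$scale)
    if (object$method == "random_forest") {
      # loading the namespace registers predict.ranger for dispatch (a
      # deserialized model may be predicted before any ranger:: call)
      requireNamespace("ranger", quietly = TRUE)
      pr <- stats::predict(object$model, data = as.data.frame(Xs),
                           num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    } else {
      as.numeric(stats::predict(object$model, xgboost::xgb.DMatrix(Xs)))
    }
  }
}

#' @export
print.pges_detector <- function(x, ...) {
  label <- switch(x$method,
                  random_forest = "random forest on EEG features",
                  gradient_boosted_trees =
                    "gradient boosted trees on EEG features",
                  cnn = "compact convolutional network on raw crops")
  cat("<pges_detector> ", label, "\n", sep = "")
  cat("  trained on ", x$n_train, " crops (",
      x$class_counts[["0"]], " in-suppression / ",
      x$class_counts[["1"]], " reaching the end)\n", sep = "")
  cat("  window ", x$spec$window_s, " s, stride ", x$spec$stride_s,
      " s at ", x$sampling_rate_hz, " Hz\n", sep = "")
  if (x$method == "cnn")
    cat("  ", x$n_params, " trainable parameters; best epoch ",
        x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' @export
summary.pges_detector <- function(object, ...) {
  print(object)
  if (object$method == "cnn") {
    h <- object$history
    cat("  training loss: ", format(h$train_loss[1], digits = 4), " -> ",
        format(h$train_loss[nrow(h)], digits = 4), " over ", nrow(h),
        " epochs\n", sep = "")
    if (any(is.finite(h$val_auc)))
      cat("  best validation AUC ",
          format(max(h$val_auc, na.rm = TRUE), digits = 4), "\n", sep = "")
  } else {
    cat("  top features by importance:\n")
    top <- utils::head(object$importance, 8)
    for (i in seq_along(top))
      cat(sprintf("    %-34s %.4g\n", names(top)[i], top[i]))
  }
  invisible(object)
}

#' Feature importances of a fitted detector
#'
#' @param object A fitted [pges_detector()] using a tree-ensemble method.
#' @param ... Unused.
#' @return Named numeric vector of importances (impurity importance for the
#'   forest, gain for boosted trees), decreasing. The CNN has no per-feature
#'   importances and returns `NULL`.
#' @export
coef.pges_detector <- function(object, ...) {
  if (object$method == "cnn") return(NULL)
  object$importance
}

#' Plot a fitted detector
#'
#' For the CNN, the training-loss and validation-AUC history; for the tree
#' ensembles, the top feature importances.
#'
#' @param x A fitted [pges_detector()].
#' @param n_features Number of importances to show (default 20).
#' @param ... Unused.
#' @export
plot.pges_detector <- function(x, n_features = 20L, ...) {
  if (x$method == "cnn") {
    h <- x$history
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    plot(h$epoch, h$train_loss, type = "b", pch = 16, xlab = "epoch",
         ylab = "training loss", main = "loss")
    if (any(is.finite(h$val_auc)))
      plot(h$epoch, h$val_auc, type = "b", pch = 16, xlab = "epoch",
           ylab = "validation AUC", main = "validation", ylim = c(0, 1))
  } else {
    imp <- utils::head(x$importance, n_features)
    op <- graphics::par(mar = c(4, 12, 2, 1))
    on.exit(graphics::par(op))
    graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                      cex.names = 0.6, xlab = "importance",
                      main = "feature importance")
  }
  invisible(x)
}
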