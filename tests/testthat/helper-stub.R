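# A stub detector whose probability is a pure function of the crop data and
# its end time — lets tracing/detection/evaluation logic be exercised
# against exactly known probabilities, without training a model.

stub_detector <- function(fun, spec = crop_spec(10, 0.5, 10), fs = 200,
                          labels = paste0("m", 1:3)) {
  structure(list(method = "stub", spec = spec,
                 sampling_rate_hz = fs, montage_labels = labels,
                 stub_fun = fun),
            class = c("stub_detector", "pges_detector"))
}

predict.stub_detector <- function(object, newdata, ...) {
  if (inherits(newdata, "eeg_montaged"))
    return(probability_trace(object, newdata, ...))
  vapply(seq_len(dim(newdata$data)[3]), function(i)
    object$stub_fun(newdata$data[, , i], newdata$index$end_s[i]), 0)
}

registerS3method("predict", "stub_detector", predict.stub_detector,
                 envir = asNamespace("stats"))
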