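#' Plot raw montage traces against the detector probability
#'
#' Stacked bipolar channels above the probability trace, with the
#' post-suppression (slow activity) region shaded from the true end of
#' suppression to the end of the plot and the called detection marked.
#'
#' @param x A `pges_trace`.
#' @param mrec The `eeg_montaged` recording the trace came from.
#' @param rule An [onset_rule()] used to mark the detection (NULL for none).
#' @param ... Unused.
#' @export
plot.pges_trace <- function(x, mrec = NULL, rule = onset_rule(), ...) {
  op <- graphics::par(mfrow = c(if (is.null(mrec)) 1 else 2, 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  truth <- x$pges_end_s
  if (!is.null(mrec)) {
    fs <- mrec$sampling_rate_hz
    t <- (seq_len(ncol(mrec$data)) - 1) / fs
    nch <- nrow(mrec$data)
    spread <- max(3 * stats::sd(mrec$data), 1e-6)
    graphics::plot(NA, xlim = range(t), ylim = c(0.5, nch + 0.5),
                   xlab = "", ylab = "montage", yaxt = "n")
    graphics::axis(2, at = seq_len(nch), labels = mrec$montage_labels,
                   las = 1, cex.axis = 0.55)
    if (!is.null(truth))
      graphics::rect(truth, 0.5, max(t), nch + 0.5,
                     col = grDevices::rgb(0.7, 0.95, 0.7, 0.5), border = NA)
    for (i in seq_len(nch))
      graphics::lines(t, i + mrec$data[i, ] / (2 * spread), lwd = 0.3)
  }
  graphics::plot(x$times_s, x$probs, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "P(end of suppression)")
  if (!is.null(truth)) {
    graphics::rect(truth, 0, max(x$times_s), 1,
                   col = grDevices::rgb(0.7, 0.95, 0.7, 0.5), border = NA)
    graphics::abline(v = truth, col = "darkgreen", lty = 2)
  }
  if (!is.null(rule)) {
    graphics::abline(h = rule$threshold, col = "grey", lty = 3)
    det <- detect_onset(x, rule)
    if (!is.na(det$detected_s))
      graphics::points(det$detected_s, rule$threshold, pch = 17,
                       col = "red", cex = 1.4)
  }
  invisible(x)
}

#' Export a trace plot to an image file
#'
#' @param mrec An `eeg_montaged` recording.
#' @param trace Its `pges_trace` (from [probability_trace()]).
#' @param path Output file (`.png` or `.svg` by extension).
#' @param rule [onset_rule()] for the detection marker, or NULL.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
export_trace_plot <- function(mrec, trace, path, rule = onset_rule(),
                              width = 1000, height = 700) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = width / 100,
                                   height = height / 100)
  else grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(trace, mrec = mrec, rule = rule)
  invisible(path)
}
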