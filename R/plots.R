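#' Plot methods
#'
#' `autoplot()` methods render the main result types with ggplot2: the PSD
#' (log-power spectra per channel), an evoked trace (GMFA or local TEP,
#' with the found component peaks marked), and the ROC curve of the
#' responder classifier.
#'
#' @param object A tmsreact result object.
#' @param channels Optional channel subset for PSD plots.
#' @param peaks Optional `peak_table` to overlay on an evoked trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tmsreact-autoplot
NULL

#' @rdname tmsreact-autoplot
#' @method autoplot eeg_psd
#' @export
autoplot.eeg_psd <- function(object, channels = NULL, ...) {
  d <- tidy(object)
  if (!is.null(channels)) d <- d[d$channel %in% channels, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$psd,
                                  group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_cartesian(xlim = c(0, 45)) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz)))
}

#' @rdname tmsreact-autoplot
#' @method autoplot evoked_trace
#' @export
autoplot.evoked_trace <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$time_ms, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)", y = expression(Amplitude ~ (mu * V)),
                  title = toupper(object$kind))
  if (!is.null(peaks)) {
    found <- peaks[peaks$found, ]
    p <- p + ggplot2::geom_point(
      data = found,
      ggplot2::aes(x = .data$latency_ms, y = .data$amplitude),
      colour = "red") +
      ggplot2::geom_text(
        data = found,
        ggplot2::aes(x = .data$latency_ms, y = .data$amplitude,
                     label = .data$component),
        vjust = -1, size = 3)
  }
  p
}

#' @rdname tmsreact-autoplot
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate")
}

#' @rdname tmsreact-autoplot
#' @method autoplot responder_clf
#' @export
autoplot.responder_clf <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(title = sprintf(
      "Nested-CV linear SVM (%d repetitions, n = %d)",
      object$settings$repetitions, object$n))
}
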