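#' Tidy methods for tmsreact result objects
#'
#' broom-style accessors: `tidy()` returns a long tibble of the object's
#' per-unit values; `glance()` a one-row summary.
#'
#' @param x A tmsreact result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tmsreact-tidiers
NULL

#' @rdname tmsreact-tidiers
#' @method tidy spectral_summary
#' @export
tidy.spectral_summary <- function(x, ...) {
  out <- x$band_power
  if (!is.null(x$ratio1)) {
    out <- dplyr::left_join(out, x$ratio1, by = "channel")
  }
  out
}

#' @rdname tmsreact-tidiers
#' @method tidy eeg_psd
#' @export
tidy.eeg_psd <- function(x, ...) {
  tibble(channel = rep(rownames(x$psd), each = length(x$freq)),
         freq = rep(x$freq, nrow(x$psd)),
         psd = as.vector(t(x$psd)))
}

#' @rdname tmsreact-tidiers
#' @method tidy pli_matrix
#' @export
tidy.pli_matrix <- function(x, ...) {
  ch <- rownames(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble(band = if (is.character(x$band)) x$band else
    paste(x$band, collapse = "-"),
    a = ch[idx[, 1]], b = ch[idx[, 2]],
    pli = x$matrix[idx])
}

#' @rdname tmsreact-tidiers
#' @method tidy evoked_trace
#' @export
tidy.evoked_trace <- function(x, ...) {
  tibble(kind = x$kind, time_ms = x$times, amplitude = x$values)
}

#' @rdname tmsreact-tidiers
#' @method tidy evoked
#' @export
tidy.evoked <- function(x, ...) {
  tibble(channel = rep(rownames(x$data), each = length(x$times)),
         time_ms = rep(x$times, nrow(x$data)),
         amplitude = as.vector(t(x$data)))
}

#' @rdname tmsreact-tidiers
#' @method tidy responder_clf
#' @export
tidy.responder_clf <- function(x, ...) x$per_rep

#' @rdname tmsreact-tidiers
#' @method glance responder_clf
#' @export
glance.responder_clf <- function(x, ...) {
  tibble(balanced_accuracy = x$balanced_accuracy, auc = x$auc,
         sensitivity = x$sensitivity, specificity = x$specificity,
         repetitions = x$settings$repetitions, n = x$n)
}

#' @rdname tmsreact-tidiers
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @rdname tmsreact-tidiers
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, threshold = x$threshold,
         sensitivity = x$sensitivity, specificity = x$specificity)
}
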