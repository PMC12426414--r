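#' Resting EEG recording container
#'
#' Wraps a channels x samples voltage matrix (microvolts) with its sampling
#' rate and montage. Rows are named by channel label in montage order.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param montage An [eeg_montage()].
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, montage) {
  abort_if(!is.matrix(data) || !is.numeric(data),
           "data must be a numeric channels x samples matrix")
  abort_if(nrow(data) != length(montage$names),
           "data must have one row per montage channel")
  rownames(data) <- montage$names
  structure(list(data = data, fs = fs, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s)\n",
      sep = "")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
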