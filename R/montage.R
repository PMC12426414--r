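#' Electrode montages
#'
#' An `eeg_montage` is an ordered set of channel labels plus named channel
#' clusters used for regional averaging. The default is the 59-channel 10-10
#' layout used for combined resting / TMS-EEG recordings, with the two
#' nine-electrode primary-motor-cortex (M1) clusters and a frontal cluster.
#'
#' @param names Character vector of unique channel labels, in recording order.
#' @param clusters Named list of character vectors; every label must appear in
#'   `names`.
#'
#' @return An object of class `eeg_montage`: a list with elements `names` and
#'   `clusters`.
#' @export
#' @examples
#' mont <- default_montage()
#' length(mont$names)
#' mont$clusters$m1_left
eeg_montage <- function(names, clusters = list()) {
  abort_if(anyDuplicated(names) > 0, "montage channel labels must be unique")
  missing <- setdiff(unlist(clusters, use.names = FALSE), names)
  abort_if(length(missing) > 0,
           paste0("cluster channel(s) not in montage: ",
                  paste(missing, collapse = ", ")),
           class = "tmsreact_lookup_error")
  structure(list(names = as.character(names), clusters = clusters),
            class = "eeg_montage")
}

#' @rdname eeg_montage
#' @export
default_montage <- function() {
  nm <- c(
    "Fp1", "Fpz", "Fp2",
    "AF3", "AFz", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
  eeg_montage(
    nm,
    clusters = list(
      m1_left  = c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1"),
      m1_right = c("FC6", "FC4", "FC2", "C6", "C4", "C2", "CP6", "CP4", "CP2"),
      frontal  = c("Fp1", "Fp2", "F7", "F3", "Fz", "F2", "F4", "F8")
    )
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$names), " channels; clusters: ",
      paste(names(x$clusters), collapse = ", "), "\n", sep = "")
  invisible(x)
}

montage_index <- function(montage, labels) {
  idx <- match(labels, montage$names)
  abort_if(anyNA(idx),
           paste0("unknown channel label(s): ",
                  paste(labels[is.na(idx)], collapse = ", ")),
           class = "tmsreact_lookup_error")
  idx
}

cluster_channels <- function(montage, cluster) {
  abort_if(!cluster %in% names(montage$clusters),
           paste0("cluster '", cluster, "' not defined in montage"))
  ch <- montage$clusters[[cluster]]
  abort_if(length(ch) == 0, paste0("cluster '", cluster, "' is empty"))
  ch
}
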