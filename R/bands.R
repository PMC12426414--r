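#' Frequency band partition
#'
#' The canonical band set for EEG slowing analyses: delta (1-4 Hz) with its
#' sub-bands delta1 (1-2) and delta2 (2-4), theta (4-8), alpha (8-13),
#' beta (13-32) and gamma (32-45). `delta`, `theta`, `alpha`, `beta`, `gamma`
#' partition the 1-45 Hz range; `delta1` and `delta2` partition `delta`.
#'
#' @param bands Optional named list of `c(low, high)` pairs in Hz; defaults to
#'   the standard partition above.
#'
#' @return A tibble of class `band_set` with columns `band`, `low`, `high`.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(
      delta = c(1, 4), delta1 = c(1, 2), delta2 = c(2, 4),
      theta = c(4, 8), alpha = c(8, 13), beta = c(13, 32), gamma = c(32, 45)
    )
  }
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  abort_if(any(lo >= hi), "every band must have low < high")
  out <- tibble(band = names(bands), low = unname(lo), high = unname(hi))
  class(out) <- c("band_set", class(out))
  out
}

band_edges <- function(bands, name) {
  i <- match(name, bands$band)
  abort_if(is.na(i), paste0("unknown band '", name, "'"),
           class = "tmsreact_lookup_error")
  c(bands$low[i], bands$high[i])
}

# Names of the bands that partition the total range (excludes sub-bands).
partition_bands <- function(bands) {
  setdiff(bands$band, c("delta1", "delta2"))
}
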