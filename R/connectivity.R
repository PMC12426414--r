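#' Band-limited instantaneous phase
#'
#' Zero-phase FIR band-pass followed by the analytic-signal (Hilbert) phase
#' per channel. A valid-sample mask excludes one filter length at each edge
#' of the record, where the filter transient contaminates the phase.
#'
#' @param rec An [eeg_recording()].
#' @param band Band name in `bands`, or a `c(low, high)` pair in Hz.
#' @param bands A [eeg_bands()] set used to resolve a band name.
#'
#' @return An object of class `phase_set`: list with `phase` (channels x
#'   samples, radians in (-pi, pi]), `mask` (valid sample indices), `band`,
#'   `fs`, `montage`.
#' @export
band_phase <- function(rec, band, bands = eeg_bands()) {
  abort_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  edges <- if (is.character(band)) band_edges(bands, band) else band
  abort_if(edges[2] >= rec$fs / 2, "band must lie below the Nyquist frequency")
  filt <- fir_bandpass(rec$fs, edges[1], edges[2])
  filtered <- filter_zerophase(rec$data, filt)
  mask <- filter_valid_mask(n_samples(rec), filt)
  structure(list(phase = analytic_phase(filtered), mask = mask,
                 band = band, band_edges = edges, fs = rec$fs,
                 montage = rec$montage),
            class = "phase_set")
}

#' Phase lag index matrix
#'
#' The phase lag index (PLI) between two channels is the absolute mean sign
#' of the sine of their instantaneous phase difference over the masked
#' samples:
#' \deqn{PLI(a,b) = | \langle sign(\sin(\phi_a(t) - \phi_b(t))) \rangle_t |}
#' It quantifies the asymmetry of the phase-difference distribution around
#' zero, and is insensitive to zero-lag (volume-conduction) coupling:
#' `sign(0)` contributes 0, so identical or purely amplitude-mixed channels
#' score 0. PLI is computed over the full masked record; optionally the
#' record can be split into epochs with one PLI per epoch averaged.
#'
#' @param phases A `phase_set` from [band_phase()].
#' @param epoch_seconds If not `NULL`, split the masked samples into
#'   consecutive epochs of this length and average per-epoch PLI values.
#'
#' @return An object of class `pli_matrix`: list with `matrix` (symmetric
#'   channels x channels, zero diagonal, entries in \[0, 1\]), `band`,
#'   `montage`.
#' @export
pli_matrix <- function(phases, epoch_seconds = NULL) {
  abort_if(!inherits(phases, "phase_set"), "phases must come from band_phase()")
  abort_if(length(phases$mask) == 0, "edge mask leaves no valid samples")
  abort_if(nrow(phases$phase) < 2L, "need at least 2 channels")
  ph <- phases$phase[, phases$mask, drop = FALSE]
  if (is.null(epoch_seconds)) {
    m <- pli_from_phase(ph)
  } else {
    len <- round(epoch_seconds * phases$fs)
    n_ep <- ncol(ph) %/% len
    abort_if(n_ep < 1L, "masked record shorter than one epoch")
    acc <- 0
    for (e in seq_len(n_ep)) {
      acc <- acc + pli_from_phase(ph[, ((e - 1L) * len + 1L):(e * len),
                                     drop = FALSE])
    }
    m <- acc / n_ep
  }
  dimnames(m) <- list(phases$montage$names, phases$montage$names)
  structure(list(matrix = m, band = phases$band, montage = phases$montage),
            class = "pli_matrix")
}

pli_from_phase <- function(ph) {
  n <- ncol(ph)
  # sign(sin(a-b)) = sign(sin a cos b - cos a sin b); computed pairwise
  nch <- nrow(ph)
  m <- matrix(0, nch, nch)
  s <- sin(ph); co <- cos(ph)
  for (a in seq_len(nch - 1L)) {
    d <- s[a, ] * t(co[(a + 1L):nch, , drop = FALSE]) -
      co[a, ] * t(s[(a + 1L):nch, , drop = FALSE])
    v <- abs(colMeans(sign(d)))
    m[a, (a + 1L):nch] <- v
    m[(a + 1L):nch, a] <- v
  }
  m
}

#' Extract one pair's PLI
#'
#' @param pli A `pli_matrix`.
#' @param a,b Channel labels; order-invariant.
#' @return The scalar PLI value for the pair.
#' @export
#' @examples
#' # pair_pli(pli, "F2", "F7")
pair_pli <- function(pli, a, b) {
  abort_if(!inherits(pli, "pli_matrix"), "pli must come from pli_matrix()")
  ia <- montage_index(pli$montage, a)
  ib <- montage_index(pli$montage, b)
  pli$matrix[ia, ib]
}

#' Band-specific connectivity in one call
#'
#' @inheritParams band_phase
#' @inheritParams pli_matrix
#' @return A `pli_matrix`.
#' @export
connectivity_matrix <- function(rec, band, bands = eeg_bands(),
                                epoch_seconds = NULL) {
  pli_matrix(band_phase(rec, band, bands), epoch_seconds)
}

#' @export
print.pli_matrix <- function(x, ...) {
  b <- if (is.character(x$band)) x$band else paste(x$band, collapse = "-")
  cat("<pli_matrix> band ", b, "; ", nrow(x$matrix), " channels\n", sep = "")
  invisible(x)
}
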