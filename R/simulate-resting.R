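#' Specification for a simulated resting EEG recording
#'
#' Describes a resting recording as band-limited oscillations over a 1/f
#' ("pink") background: each named band receives a target fraction of the
#' total oscillatory variance, optional channel pairs share a band-limited
#' component with a constant phase lag, and white sensor noise is added on
#' top. All amplitudes are in microvolts.
#'
#' @param duration Recording length in seconds (>= 4).
#' @param fs Sampling rate in Hz (default 1000).
#' @param band_fractions Named numeric vector mapping band name (see
#'   [eeg_bands()]) to its target share of the oscillatory variance;
#'   nonnegative, summing to at most 1. The remainder goes to the pink
#'   background.
#' @param pink_exponent Spectral slope a of the 1/f^a background (default 1).
#' @param coupled_pairs List of [coupled_pair()] entries.
#' @param noise_sd White sensor-noise standard deviation in microvolts.
#' @param signal_var Total oscillatory variance budget per channel, in
#'   microvolts squared (default 100).
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, montage).
#'
#' @return A `resting_sim_spec` list.
#' @export
resting_sim_spec <- function(duration, fs = 1000,
                             band_fractions = c(delta = 0.2, theta = 0.15,
                                                alpha = 0.3, beta = 0.15,
                                                gamma = 0.05),
                             pink_exponent = 1, coupled_pairs = list(),
                             noise_sd = 1, signal_var = 100, seed = 1) {
  abort_if(duration < 4, "duration must be at least 4 seconds")
  abort_if(any(band_fractions < 0), "band fractions must be nonnegative")
  abort_if(sum(band_fractions) > 1 + 1e-12,
           "band fractions must sum to at most 1")
  structure(list(duration = duration, fs = fs,
                 band_fractions = band_fractions,
                 pink_exponent = pink_exponent,
                 coupled_pairs = coupled_pairs, noise_sd = noise_sd,
                 signal_var = signal_var, seed = seed),
            class = "resting_sim_spec")
}

#' @param a,b Channel labels sharing the component.
#' @param band Band name the shared component is limited to.
#' @param lag Constant phase lag in radians (channel `b` lags `a`).
#' @param var Variance of the shared component in each channel (microvolts
#'   squared); defaults to the spec's `signal_var` at simulation time, which
#'   makes the pair's coupling dominate that band.
#' @rdname resting_sim_spec
#' @export
coupled_pair <- function(a, b, band, lag, var = NULL) {
  list(a = a, b = b, band = band, lag = lag, var = var)
}

#' Simulate a resting EEG recording
#'
#' Generates a channels x samples matrix in which each channel carries
#' independent band-limited components (white noise shaped in the Fourier
#' domain by a half-sine spectral envelope over the band - a unimodal,
#' rhythm-like spectrum wholly contained in its band - then
#' variance-rescaled to hit the requested band fractions exactly), a 1/f^a pink background band-limited to 1-45 Hz taking
#' the remaining variance, white sensor noise, and - for each coupled pair -
#' a shared band-limited component whose copy in channel `b` is rotated by a
#' constant phase lag at every frequency (Fourier-domain phase rotation).
#'
#' @param spec A [resting_sim_spec()].
#' @param montage An [eeg_montage()]; default [default_montage()].
#' @param bands A [eeg_bands()] band set naming the bands in
#'   `spec$band_fractions`.
#'
#' @return An [eeg_recording()].
#' @export
#' @examples
#' spec <- resting_sim_spec(duration = 8, band_fractions = c(alpha = 1),
#'                          pink_exponent = 0, noise_sd = 0, seed = 42)
#' rec <- simulate_resting_eeg(spec, default_montage())
#' rec
simulate_resting_eeg <- function(spec, montage = default_montage(),
                                 bands = eeg_bands()) {
  abort_if(!inherits(spec, "resting_sim_spec"), "spec must be a resting_sim_spec")
  edges <- lapply(names(spec$band_fractions), band_edges, bands = bands)
  hi_edge <- max(c(0, vapply(edges, `[`, numeric(1), 2L)))
  abort_if(spec$fs <= 2 * hi_edge,
           "sampling rate must exceed twice the highest band edge")
  for (cp in spec$coupled_pairs) montage_index(montage, c(cp$a, cp$b))

  nch <- length(montage$names)
  ns <- round(spec$duration * spec$fs)

  with_seed(spec$seed, {
    x <- matrix(0, nch, ns)

    # independent band-limited oscillations, exact variance control
    for (i in seq_along(spec$band_fractions)) {
      frac <- spec$band_fractions[[i]]
      if (frac <= 0) next
      comp <- band_noise_matrix(nch, ns, spec$fs, edges[[i]])
      comp <- comp / apply(comp, 1, sd) * sqrt(frac * spec$signal_var)
      x <- x + comp
    }

    # pink 1/f^a background over 1-45 Hz with the leftover variance
    pink_var <- (1 - sum(spec$band_fractions)) * spec$signal_var
    if (pink_var > 1e-12) {
      x <- x + pink_noise_matrix(nch, ns, spec$fs, spec$pink_exponent,
                                 pink_var)
    }

    # shared phase-lagged components
    for (cp in spec$coupled_pairs) {
      e <- band_edges(bands, cp$band)
      s <- drop(band_noise_matrix(1L, ns, spec$fs, e))
      s <- s / sd(s) * sqrt(cp$var %||% spec$signal_var)
      ia <- montage_index(montage, cp$a)
      ib <- montage_index(montage, cp$b)
      x[ia, ] <- x[ia, ] + s
      x[ib, ] <- x[ib, ] + rotate_phase(s, cp$lag)
    }

    if (spec$noise_sd > 0) {
      x <- x + matrix(rnorm(nch * ns, sd = spec$noise_sd), nch, ns)
    }
    eeg_recording(x, spec$fs, montage)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# White noise band-limited in the Fourier domain with a half-sine spectral
# envelope over the band: a unimodal rhythm peaked at band centre, zero at
# the edges. Exact band containment makes the band-fraction bookkeeping
# exact, and the edge taper keeps spectral-estimation leakage inside the
# band.
band_noise_matrix <- function(nch, ns, fs, edges) {
  freqs <- seq(0, fs - fs / ns, length.out = ns)
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]
  gain <- numeric(ns)
  sel <- freqs >= edges[1] & freqs <= edges[2]
  gain[sel] <- sin(pi * (freqs[sel] - edges[1]) / (edges[2] - edges[1]))
  X <- stats::mvfft(matrix(rnorm(nch * ns), ns, nch)) * gain
  t(Re(stats::mvfft(X, inverse = TRUE)) / ns)
}

# 1/f^a noise band-limited to band_lim, scaled to total variance target_var.
pink_noise_matrix <- function(nch, ns, fs, exponent, target_var,
                              band_lim = c(1, 45)) {
  freqs <- seq(0, fs - fs / ns, length.out = ns)
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]   # two-sided axis
  gain <- numeric(ns)
  sel <- freqs >= band_lim[1] & freqs <= band_lim[2]
  gain[sel] <- freqs[sel]^(-exponent / 2)
  X <- stats::mvfft(matrix(rnorm(nch * ns), ns, nch)) * gain
  x <- t(Re(stats::mvfft(X, inverse = TRUE)) / ns)
  x / apply(x, 1, sd) * sqrt(target_var)
}
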