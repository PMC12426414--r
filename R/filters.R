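# FIR band-pass design and zero-phase application.
#
# Kernels are linear-phase (symmetric) Hamming-windowed FIRs from
# signal::fir1; they are applied in a single pass by FFT convolution with the
# group delay removed, which for a symmetric kernel is exactly zero-phase.
# The order guarantees >= 3 cycles of the band's low edge so that delta-band
# phase estimates are usable; the edge mask excludes one kernel length at
# each end of the record.

fir_bandpass <- function(fs, low, high, cycles = 3) {
  abort_if(high >= fs / 2, "band must lie strictly below the Nyquist frequency")
  abort_if(low <= 0 || low >= high, "band edges must satisfy 0 < low < high")
  ord <- ceiling(cycles * fs / low)
  if (ord %% 2L == 1L) ord <- ord + 1L          # even order -> integer group delay
  h <- signal::fir1(ord, c(low, high) * 2 / fs, type = "pass")
  structure(list(h = as.numeric(h), order = ord, fs = fs,
                 band = c(low, high)),
            class = "fir_filter")
}

# Zero-phase filtering of a channels x samples matrix (or a vector).
filter_zerophase <- function(x, filt) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  ns <- ncol(x)
  h <- filt$h
  gd <- filt$order / 2L
  nfft <- stats::nextn(ns + length(h) - 1L, 2)
  H <- fft(c(h, numeric(nfft - length(h))))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - ns, nrow(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  out <- t(y[(gd + 1L):(gd + ns), , drop = FALSE])
  if (vec) out <- drop(out)
  out
}

# Sample indices free of filter edge transients: one kernel length per edge.
filter_valid_mask <- function(n_samples, filt) {
  edge <- length(filt$h)
  abort_if(n_samples <= 2L * edge,
           "recording too short for the filter's edge mask")
  seq.int(edge + 1L, n_samples - edge)
}

# Instantaneous phase of the analytic signal (FFT Hilbert transform),
# per row of a channels x samples matrix. Returns phases in (-pi, pi].
analytic_phase <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2L + 1L] <- 1
    w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2L:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(t(x)) * w
  z <- stats::mvfft(X, inverse = TRUE) / n
  ph <- t(Arg(z))
  if (vec) ph <- drop(ph)
  ph
}

# Rotate the phase of every (positive-frequency) Fourier component of a real
# signal by `phi` radians, i.e. delay each sinusoidal component by phi of its
# own cycle. DC and Nyquist are left untouched. Returns a real signal.
rotate_phase <- function(x, phi) {
  n <- length(x)
  X <- fft(x)
  half <- if (n %% 2L == 0L) n / 2L else (n + 1L) / 2L
  idx_pos <- 2L:half
  X[idx_pos] <- X[idx_pos] * exp(-1i * phi)
  # mirror for conjugate symmetry
  idx_neg <- n + 2L - idx_pos
  X[idx_neg] <- Conj(X[idx_pos])
  Re(fft(X, inverse = TRUE)) / n
}
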