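# Small fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (explicit loops, textbook formulas) and
# share no code with the package internals they check.

two_channel_montage <- function(labels = c("F2", "F7")) {
  eeg_montage(labels)
}

sine_recording <- function(freq_hz, amp, duration_s, fs = 1000,
                           labels = c("A", "B")) {
  t <- seq_len(duration_s * fs) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq_hz * t), length(labels)),
              nrow = length(labels), byrow = TRUE)
  eeg_recording(x, fs, eeg_montage(labels))
}

# Brute-force Welch estimate: explicit per-segment loop, Hann window,
# manual periodogram averaging with the one-sided density normalisation.
oracle_welch <- function(x, fs, nper, noverlap) {
  step <- nper - noverlap
  starts <- seq(1, length(x) - nper + 1, by = step)
  k <- 0:(nper - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (nper - 1)))
  nfreq <- nper %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nfreq]
    acc <- acc + Mod(X)^2
  }
  p <- acc / length(starts) / (fs * sum(w^2))
  p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
  p
}

# Per-timepoint population standard deviation across channels.
oracle_gmfa <- function(m) {
  apply(m, 2, function(v) sqrt(mean((v - mean(v))^2)))
}

# Pairwise-comparison AUC: every positive-negative pair, ties count half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Direct restatement of the responder rule.
oracle_responder <- function(t0, t10) {
  rate_ok <- (t0 - t10) / t0 >= 0.30
  points_ok <- (t0 - t10) > 5
  if (rate_ok || points_ok) "responder" else "non-responder"
}
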