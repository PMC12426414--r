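test_that("band-limited phase advances at the sinusoid's frequency", {
  rec <- sine_recording(10, 1, 20)
  ph <- band_phase(rec, "alpha")
  un <- cumsum(c(ph$phase[1, ph$mask][1],
                 atan2(sin(diff(ph$phase[1, ph$mask])),
                       cos(diff(ph$phase[1, ph$mask])))))
  slope <- (un[length(un)] - un[1]) / (length(un) - 1) * rec$fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
})

test_that("identical channels have zero phase difference and PLI 0", {
  rec <- sine_recording(10, 1, 20)
  ph <- band_phase(rec, "alpha")
  expect_equal(max(abs(ph$phase[1, ph$mask] - ph$phase[2, ph$mask])), 0,
               tolerance = 1e-10)
  expect_equal(pair_pli(pli_matrix(ph), "A", "B"), 0)
})

test_that("a quarter-period delay at 10 Hz shows as a pi/2 phase difference", {
  fs <- 1000
  t <- seq_len(20 * fs) / fs
  x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * (t - 0.025)))
  rec <- eeg_recording(x, fs, two_channel_montage(c("A", "B")))
  ph <- band_phase(rec, "alpha")
  d <- ph$phase[1, ph$mask] - ph$phase[2, ph$mask]
  d <- atan2(sin(d), cos(d))
  expect_equal(mean(d), pi / 2, tolerance = 0.05)
  # cross-check against the FFT cross-spectrum phase at 10 Hz
  X <- stats::fft(x[1, ]); Y <- stats::fft(x[2, ])
  k <- 10 * 20 + 1
  expect_equal(Arg(X[k] * Conj(Y[k])), pi / 2, tolerance = 0.05)
})

test_that("constant-lag coupling gives PLI 1, volume conduction gives ~0", {
  mont <- two_channel_montage()
  spec <- resting_sim_spec(duration = 30, band_fractions = c(alpha = 1),
                           noise_sd = 0,
                           coupled_pairs = list(
                             coupled_pair("F2", "F7", "delta", pi / 2)),
                           seed = 8)
  rec <- simulate_resting_eeg(spec, mont)
  expect_equal(pair_pli(connectivity_matrix(rec, "delta"), "F2", "F7"), 1,
               tolerance = 1e-6)

  # one source mixed into both channels with zero lag, arbitrary weights
  set.seed(3)
  src <- drop(band_noise_matrix(1L, 30000, 1000, c(8, 13)))
  mix <- eeg_recording(rbind(0.3 * src, 1.7 * src), 1000, mont)
  expect_lte(pair_pli(connectivity_matrix(mix, "alpha"), "F2", "F7"), 0.05)
})

test_that("PLI is invariant to per-channel amplitude scaling and channel swap", {
  spec <- resting_sim_spec(duration = 10, seed = 14)
  rec <- simulate_resting_eeg(spec, two_channel_montage())
  m1 <- connectivity_matrix(rec, "alpha")$matrix
  rec2 <- rec
  rec2$data[1, ] <- rec2$data[1, ] * 7.3
  m2 <- connectivity_matrix(rec2, "alpha")$matrix
  expect_equal(max(abs(m1 - m2)), 0, tolerance = 1e-12)
  rec3 <- rec
  rec3$data <- rec3$data[c(2, 1), ]
  m3 <- connectivity_matrix(rec3, "alpha")$matrix
  expect_equal(m3[1, 2], m1[1, 2], tolerance = 1e-12)
})

test_that("independent white-noise channels stay near the PLI null", {
  # the null magnitude is |mean of +/-1 signs| over the effective number of
  # independent phase-difference samples, so narrow bands sit higher; the
  # seed-averaged null must stay well below coupled-pair values
  vals <- vapply(1:8, function(s) {
    set.seed(100 + s)
    rec <- eeg_recording(matrix(rnorm(2 * 60000), 2), 1000,
                         two_channel_montage())
    pair_pli(connectivity_matrix(rec, "delta"), "F2", "F7")
  }, numeric(1))
  expect_lte(mean(vals), 0.1)
  expect_lte(max(vals), 0.25)
})

test_that("PLI matrices are symmetric, zero-diagonal, in [0, 1]", {
  spec <- resting_sim_spec(duration = 8, seed = 2)
  mont <- eeg_montage(c("F2", "F7", "Cz"))
  m <- connectivity_matrix(simulate_resting_eeg(spec, mont), "alpha")
  expect_equal(m$matrix, t(m$matrix))
  expect_equal(unname(diag(m$matrix)), rep(0, 3))
  expect_true(all(m$matrix >= 0 & m$matrix <= 1))
  expect_identical(pair_pli(m, "F2", "F7"), pair_pli(m, "F7", "F2"))
  expect_identical(pair_pli(m, "F2", "F2"), 0)
  expect_error(pair_pli(m, "F2", "Qz"), class = "tmsreact_lookup_error")
})
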