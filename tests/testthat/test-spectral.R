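test_that("a pure sinusoid's integrated power recovers A^2/2", {
  rec <- sine_recording(10, 2, 60)
  psd <- welch_psd(rec)
  # full main lobe of the 10-Hz line (Hann leakage spans +/- 1 bin)
  expect_equal(integrate_psd_row(psd$freq, psd$psd[1, ], 9, 11), 2,
               tolerance = 0.05)
  s <- relative_band_power(psd)
  bp <- s$band_power[s$band_power$channel == "A", ]
  expect_gte(bp$rel_power[bp$band == "alpha"], 0.99)
  expect_true(all(bp$rel_power[!bp$band %in% c("alpha")] <= 0.01))
})

test_that("zero signal gives an all-zero PSD and an undefined-ratio error", {
  mont <- two_channel_montage(c("A", "B"))
  rec <- eeg_recording(matrix(0, 2, 8000), 1000, mont)
  psd <- welch_psd(rec)
  expect_true(all(psd$psd == 0))
  expect_error(relative_band_power(psd), class = "tmsreact_undefined_ratio")
})

test_that("white-noise PSD integrates to the signal variance", {
  mont <- eeg_montage("A")
  set.seed(11)
  ints <- replicate(5, {
    rec <- eeg_recording(matrix(rnorm(120000), 1), 1000, mont)
    psd <- welch_psd(rec)
    integrate_psd_row(psd$freq, psd$psd[1, ], 0, 500)
  })
  expect_true(all(ints > 0.9 & ints < 1.1))
})

test_that("equal-power 2 Hz + 10 Hz sinusoids split delta and alpha evenly", {
  fs <- 1000
  t <- seq_len(60 * fs) / fs
  x <- matrix(sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t), 1)
  s <- resting_spectral(eeg_recording(x, fs, eeg_montage("A")))
  bp <- s$band_power
  expect_equal(bp$rel_power[bp$band == "delta"], 0.5, tolerance = 0.02)
  expect_equal(bp$rel_power[bp$band == "alpha"], 0.5, tolerance = 0.02)
})

test_that("partition identities hold on band-limited signals", {
  spec <- resting_sim_spec(duration = 20, noise_sd = 0, seed = 13)
  s <- resting_spectral(simulate_resting_eeg(spec, two_channel_montage()))
  bp <- s$band_power
  for (ch in unique(bp$channel)) {
    b <- bp[bp$channel == ch, ]
    part <- sum(b$rel_power[b$band %in% c("delta", "theta", "alpha",
                                          "beta", "gamma")])
    expect_equal(part, 1, tolerance = 1e-6)
    expect_equal(b$rel_power[b$band == "delta1"] +
                   b$rel_power[b$band == "delta2"],
                 b$rel_power[b$band == "delta"], tolerance = 1e-9)
  }
})

test_that("Welch matches a brute-force periodogram-averaging oracle", {
  set.seed(21)
  x <- rnorm(10000)
  rec <- eeg_recording(matrix(x, 1), 1000, eeg_montage("A"))
  psd <- welch_psd(rec)
  expect_equal(max(abs(psd$psd[1, ] - oracle_welch(x, 1000, 2000, 1000))), 0,
               tolerance = 1e-8)
})

test_that("scaling the signal scales absolute power by c^2, leaves relatives alone", {
  spec <- resting_sim_spec(duration = 12, noise_sd = 0, seed = 5)
  rec <- simulate_resting_eeg(spec, eeg_montage("A"))
  s1 <- resting_spectral(rec)
  rec$data <- rec$data * 3
  s2 <- resting_spectral(rec)
  expect_equal(s2$band_power$abs_power, 9 * s1$band_power$abs_power,
               tolerance = 1e-10)
  expect_equal(s2$band_power$rel_power, s1$band_power$rel_power,
               tolerance = 1e-12)
  expect_equal(s2$ratio1$ratio1, s1$ratio1$ratio1, tolerance = 1e-12)
})

test_that("Welch relative power is stable as the record gets longer", {
  rels <- vapply(c(30, 60, 120), function(dur) {
    spec <- resting_sim_spec(duration = dur, noise_sd = 0, seed = 31)
    s <- resting_spectral(simulate_resting_eeg(spec, eeg_montage("A")))
    s$band_power$rel_power[s$band_power$band == "alpha"]
  }, numeric(1))
  expect_true(all(abs(diff(rels)) / rels[-3] < 0.05))
})

test_that("the slowing ratio follows (delta + theta) / (alpha + beta)", {
  fake <- function(d, th, a, b) {
    structure(list(band_power = tibble::tibble(
      channel = "A",
      band = c("delta", "theta", "alpha", "beta"),
      abs_power = c(d, th, a, b),
      rel_power = c(d, th, a, b) / (d + th + a + b)
    )), class = "spectral_summary")
  }
  expect_equal(slow_fast_ratio(fake(3, 1, 2, 2))$ratio1, 1.0)
  expect_equal(slow_fast_ratio(fake(4, 0, 1, 1))$ratio1, 2.0)
  expect_error(slow_fast_ratio(fake(1, 1, 0, 0)),
               class = "tmsreact_undefined_ratio")
})

test_that("region averages are unweighted means over cluster channels", {
  mont <- eeg_montage(c("F3", "F4", "Cz"),
                      clusters = list(front = c("F3", "F4"), one = "Cz"))
  fake <- structure(list(
    band_power = tibble::tibble(
      channel = rep(c("F3", "F4", "Cz"), each = 1),
      band = "delta",
      abs_power = c(3, 5, 7), rel_power = c(0.3, 0.5, 0.7)
    ),
    psd = list(montage = mont)
  ), class = "spectral_summary")
  expect_equal(region_average(fake, "front", band = "delta"), 0.4)
  expect_equal(region_average(fake, "one", band = "delta"), 0.7)
  expect_error(region_average(fake, "nope", band = "delta"), "cluster")
})
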