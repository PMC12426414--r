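make_epochs <- function(data, fs = 1000, mont = two_channel_montage()) {
  times <- seq(-1000, 1000, by = 1000 / fs)
  tep_epochs(data, times, fs, mont)
}

test_that("epoching cuts one window per event and drops edge events", {
  mont <- two_channel_montage()
  fs <- 1000
  x <- matrix(seq_len(2 * 310 * fs), 2, byrow = TRUE)
  rec <- eeg_recording(x, fs, mont)
  events <- 1.5 + (0:99) * 3
  ep <- epoch_tms(rec, events)
  expect_equal(dim(ep$data), c(100, 2, 2001))
  # the t = 0 sample is the sample at the pulse time
  expect_equal(ep$data[1, 1, ep$times == 0], x[1, round(1.5 * fs) + 1])
  expect_warning(ep2 <- epoch_tms(rec, c(0.5, events)), "dropped")
  expect_equal(dim(ep2$data)[1], 100)
  expect_equal(ep2$dropped_events, 1)
})

test_that("a constant channel yields constant epochs", {
  rec <- eeg_recording(matrix(7, 2, 10000), 1000, two_channel_montage())
  ep <- epoch_tms(rec, c(2, 5), window = c(-500, 500))
  expect_true(all(ep$data == 7))
})

test_that("artifact interpolation reproduces a line and leaves outside samples untouched", {
  times <- seq(-1000, 1000)
  line <- 0.01 * times + 2
  d <- array(0, c(1, 2, 2001))
  d[1, 1, ] <- line
  d[1, 2, ] <- line
  spike <- times > -5 & times < 15
  d[1, 1, spike] <- d[1, 1, spike] + 300
  ep <- make_epochs(d)
  out <- interpolate_artifact(ep)
  expect_equal(max(abs(out$data[1, 1, ] - line)), 0, tolerance = 1e-9)
  outside <- !(times > -5 & times < 15)
  # channel 2 had no spike: bit-identical outside, and inside too (cubic on a line)
  expect_identical(out$data[1, 2, outside], ep$data[1, 2, outside])
  expect_equal(out$interpolated_window, c(-5, 15))
})

test_that("interpolating a clean noisy epoch stays within the noise scale", {
  set.seed(4)
  mont <- two_channel_montage()
  spec <- tep_sim_spec(n_trials = 1, noise_sd = 1, seed = 9)
  ep <- simulate_tep_epochs(spec, mont)
  out <- interpolate_artifact(ep)
  inside <- ep$times > -5 & ep$times < 15
  expect_lte(max(abs(out$data[1, , inside] - ep$data[1, , inside])), 5)
  expect_identical(out$data[1, , !inside], ep$data[1, , !inside])
})

test_that("amplitude rejection removes exactly the offending trials", {
  d <- array(0, c(3, 2, 2001))
  d[2, 1, 1200] <- 500                       # +200 ms excursion
  ep <- make_epochs(d)
  ep$interpolated_window <- c(-5, 15)
  out <- reject_epochs(ep)
  expect_equal(out$rejected_trials, 2L)
  expect_equal(dim(out$data)[1], 2)

  d2 <- array(0, c(3, 2, 2001))
  d2[2, 1, 1006] <- 500                      # +5 ms, inside excluded window
  ep2 <- make_epochs(d2)
  ep2$interpolated_window <- c(-5, 15)
  expect_length(reject_epochs(ep2)$rejected_trials, 0)

  d3 <- array(40, c(2, 2, 2001))             # all within +/- 50
  expect_length(reject_epochs(make_epochs(d3))$rejected_trials, 0)

  d4 <- array(500, c(2, 2, 2001))
  expect_error(reject_epochs(make_epochs(d4)),
               class = "tmsreact_pipeline_error")
})

test_that("averaging baseline-corrects and cancels symmetric trials", {
  d <- array(0, c(2, 2, 2001))
  d[1, , ] <- 1
  d[2, , ] <- -1
  ev <- average_tep(make_epochs(d))
  expect_true(all(ev$data == 0))

  set.seed(2)
  d2 <- array(rnorm(2 * 2 * 2001), c(2, 2, 2001))
  ev2 <- average_tep(make_epochs(d2))
  bl <- ev2$times >= -500 & ev2$times <= -50
  expect_equal(max(abs(rowMeans(ev2$data[, bl]))), 0, tolerance = 1e-9)
})

test_that("GMFA equals the across-channel population SD with its invariances", {
  mont4 <- eeg_montage(c("a", "b", "c", "d"))
  m <- matrix(c(1, -1, 0, 0), 4, 1)
  ev <- structure(list(data = matrix(c(1, -1), 2, 1), times = 0,
                       montage = two_channel_montage(), n_trials = 1,
                       baseline = NULL), class = "evoked")
  expect_equal(gmfa(ev)$values, 1)

  ev4 <- structure(list(data = matrix(c(2, 2, -2, -2), 4, 1), times = 0,
                        montage = mont4, n_trials = 1, baseline = NULL),
                   class = "evoked")
  expect_equal(gmfa(ev4)$values, 2)

  set.seed(6)
  r <- matrix(rnorm(59 * 40), 59)
  evr <- structure(list(data = r, times = seq_len(40), montage = default_montage(),
                        n_trials = 1, baseline = NULL), class = "evoked")
  expect_equal(max(abs(gmfa(evr)$values - oracle_gmfa(r))), 0,
               tolerance = 1e-12)
  # common offset invariance and |c| scaling
  evo <- evr; evo$data <- evo$data + 100
  expect_equal(gmfa(evo)$values, gmfa(evr)$values, tolerance = 1e-10)
  evs <- evr; evs$data <- evs$data * -3
  expect_equal(gmfa(evs)$values, 3 * gmfa(evr)$values, tolerance = 1e-10)
  # spatially uniform -> identically zero; single channel -> error
  evu <- evr; evu$data <- matrix(5, 59, 40)
  expect_true(all(gmfa(evu)$values == 0))
  ev1 <- evr; ev1$data <- evr$data[1, , drop = FALSE]
  expect_error(gmfa(ev1), "2 channels")
})

test_that("local TEP averages the cluster and sees lateralized components", {
  mont <- default_montage()
  spec <- tep_sim_spec(
    n_trials = 2, noise_sd = 0, seed = 1,
    components = list(tep_component(
      "P60", 60, 5, 10,
      topography = stats::setNames(rep(1, 9), mont$clusters$m1_left))))
  ev <- average_tep(simulate_tep_epochs(spec, mont))
  left <- local_tep(ev, "m1_left")
  right <- local_tep(ev, "m1_right")
  expect_equal(left$values[left$times == 60], 5)
  expect_equal(right$values[right$times == 60], 0)
  # GMFA of a 9-of-59-channel pattern: sqrt(9/59 - (9/59)^2) * 5
  g <- gmfa(ev)
  expect_equal(g$values[g$times == 60], 5 * sqrt(9 / 59 - (9 / 59)^2),
               tolerance = 1e-9)
  expect_lt(g$values[g$times == 60], 5)
})

test_that("peak extraction finds sign-appropriate extrema with the stated tie-breaks", {
  times <- seq(-1000, 1000)
  bump <- function(lat, amp, w) amp * exp(-(times - lat)^2 / (2 * w^2))
  tr <- evoked_trace("local", times, bump(60, 5, 8), 1, NULL)
  pk <- extract_peaks(tr)
  expect_equal(pk$latency_ms[pk$component == "P60"], 60)
  expect_equal(pk$amplitude[pk$component == "P60"], 5)

  # monotone trace over P30's window: no interior extremum
  mono <- evoked_trace("local", times, 0.001 * times, 1, NULL)
  expect_false(extract_peaks(mono)$found[1])

  # two local maxima in the P60 window: the larger (70 ms, 6) wins
  two <- evoked_trace("local", times, bump(62, 4, 2) + bump(70, 6, 2), 1, NULL)
  pk2 <- extract_peaks(two)
  expect_equal(pk2$latency_ms[pk2$component == "P60"], 70)
  expect_equal(pk2$amplitude[pk2$component == "P60"], 6, tolerance = 1e-2)

  # N100 is a trough on channel-level traces...
  neg <- evoked_trace("local", times, bump(110, -4, 10), 1, NULL)
  pk3 <- extract_peaks(neg)
  expect_true(pk3$found[pk3$component == "N100"])
  expect_equal(pk3$amplitude[pk3$component == "N100"], -4)
  # ...but a maximum on the nonnegative GMFA trace
  gtr <- evoked_trace("gmfa", times, abs(bump(110, -4, 10)), 1, NULL)
  pk4 <- extract_peaks(gtr)
  expect_equal(pk4$amplitude[pk4$component == "N100"], 4)
})

test_that("M1 side mapping follows the contralateral rule and is an involution", {
  expect_equal(map_m1_sides("right")$M1plus, "left")
  expect_equal(map_m1_sides("left")$M1plus, "right")
  for (s in c("left", "right")) {
    expect_equal(map_m1_sides(map_m1_sides(s)$M1plus)$M1plus, s)
  }
  expect_error(map_m1_sides("both"), "left")
})

test_that("increasing a planted P60 strictly increases the GMFA peak", {
  mont <- default_montage()
  topo <- stats::setNames(rep(1, 9), mont$clusters$m1_left)
  peaks <- vapply(c(2, 3, 4, 5, 6), function(a) {
    spec <- tep_sim_spec(n_trials = 3,
                         components = list(tep_component("P60", 60, a, 10,
                                                         topography = topo)),
                         noise_sd = 0.5, seed = 7)
    ep <- simulate_tep_epochs(spec, mont)
    pk <- extract_peaks(gmfa(average_tep(ep)))
    pk$amplitude[pk$component == "P60"]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
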