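#' Welch power spectral density
#'
#' One-sided Welch PSD estimate per channel: the recording is cut into
#' `segment_seconds`-long segments with `overlap_fraction` overlap, each
#' segment is mean-detrended and Hann-windowed, and windowed periodograms are
#' averaged. With 2-s segments at 1000 Hz the frequency grid has 0.5-Hz
#' resolution. Density normalisation is such that the integral of the PSD
#' over frequency approximates the signal variance (units: microvolts
#' squared per Hz).
#'
#' @param rec An [eeg_recording()].
#' @param segment_seconds Segment length in seconds (default 2).
#' @param overlap_fraction Fractional overlap between consecutive segments
#'   (default 0.5).
#'
#' @return An object of class `eeg_psd`: list with `psd` (channels x
#'   frequencies matrix), `freq` (Hz), `fs`, `montage`, `n_segments`.
#' @export
#' @examples
#' mont <- eeg_montage(c("A", "B"))
#' t <- seq(0, 10, by = 1 / 250)[-1]
#' x <- rbind(2 * sin(2 * pi * 10 * t), sin(2 * pi * 6 * t))
#' psd <- welch_psd(eeg_recording(x, 250, mont))
#' psd$freq[which.max(psd$psd[1, ])]  # 10 Hz
welch_psd <- function(rec, segment_seconds = 2, overlap_fraction = 0.5) {
  abort_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  fs <- rec$fs
  nper <- round(segment_seconds * fs)
  ns <- n_samples(rec)
  abort_if(ns < nper, "recording shorter than one Welch segment")
  step <- max(1L, round(nper * (1 - overlap_fraction)))
  starts <- seq.int(1L, ns - nper + 1L, by = step)
  abort_if(length(starts) < 2L, "recording must span at least two segments")

  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, nper - 1L) / (nper - 1L)) # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * fs / nper

  psd <- matrix(0, nrow(rec$data), nfreq,
                dimnames = list(rec$montage$names, NULL))
  for (ch in seq_len(nrow(rec$data))) {
    seg <- vapply(starts, function(s) rec$data[ch, s:(s + nper - 1L)],
                  numeric(nper))
    seg <- sweep(seg, 2L, colMeans(seg))            # per-segment detrend
    X <- stats::mvfft(seg * w)[seq_len(nfreq), , drop = FALSE]
    p <- rowMeans(Mod(X)^2) * scale
    p[c(-1L, -nfreq)] <- 2 * p[c(-1L, -nfreq)]      # one-sided doubling
    psd[ch, ] <- p
  }
  structure(list(psd = psd, freq = freq, fs = fs, montage = rec$montage,
                 n_segments = length(starts)),
            class = "eeg_psd")
}

# Trapezoidal integral of one PSD row over [low, high]; interpolates the
# edges if they fall between grid points.
integrate_psd_row <- function(freq, p, low, high) {
  inside <- freq > low & freq < high
  xs <- c(low, freq[inside], high)
  ys <- c(stats::approx(freq, p, xout = c(low, high))$y)
  trapz_int(xs, c(ys[1], p[inside], ys[2]))
}

#' Absolute and relative band power
#'
#' Integrates the Welch PSD over each band of a [eeg_bands()] partition
#' (trapezoid rule; adjacent bands share their edge, counted half in each, so
#' delta1 + delta2 equals delta exactly and the partition powers sum to the
#' total). Relative power divides each band's absolute power by the total
#' power over `total_range`, the union of the defined bands.
#'
#' @param psd An `eeg_psd` from [welch_psd()].
#' @param bands A [eeg_bands()] band set.
#' @param total_range Length-2 numeric, the denominator range in Hz.
#'
#' @return An object of class `spectral_summary`: list with `band_power`
#'   (tibble: channel, band, abs_power, rel_power), `total_power` (per
#'   channel), the `psd` object, and `bands`.
#' @export
relative_band_power <- function(psd, bands = eeg_bands(),
                                total_range = c(1, 45)) {
  abort_if(!inherits(psd, "eeg_psd"), "psd must come from welch_psd()")
  abort_if(min(psd$freq) > total_range[1] || max(psd$freq) < total_range[2],
           "frequency grid does not cover total_range")
  chans <- rownames(psd$psd)
  total <- vapply(seq_along(chans), function(ch) {
    integrate_psd_row(psd$freq, psd$psd[ch, ], total_range[1], total_range[2])
  }, numeric(1))
  abort_if(any(total <= 0),
           "total power is zero on some channel; relative power undefined",
           class = "tmsreact_undefined_ratio")

  bp <- tidyr::expand_grid(channel = chans, band = bands$band)
  bp$abs_power <- purrr::map2_dbl(bp$channel, bp$band, function(ch, b) {
    e <- band_edges(bands, b)
    integrate_psd_row(psd$freq, psd$psd[match(ch, chans), ], e[1], e[2])
  })
  bp$rel_power <- bp$abs_power / total[match(bp$channel, chans)]

  structure(list(band_power = bp,
                 total_power = stats::setNames(total, chans),
                 psd = psd, bands = bands, total_range = total_range),
            class = "spectral_summary")
}

#' Slow/fast spectral ratio (slowing index)
#'
#' Computes, per channel, ratio 1 = (delta + theta) / (alpha + beta) from the
#' absolute band powers (equivalently from relative powers; the shared
#' denominator cancels).
#'
#' @param summary A `spectral_summary` from [relative_band_power()].
#' @return A tibble with columns `channel` and `ratio1`.
#' @export
slow_fast_ratio <- function(summary) {
  abort_if(!inherits(summary, "spectral_summary"),
           "summary must come from relative_band_power()")
  wide <- tidyr::pivot_wider(summary$band_power[, c("channel", "band", "abs_power")],
                             names_from = "band", values_from = "abs_power")
  denom <- wide$alpha + wide$beta
  abort_if(any(denom <= 0),
           "alpha + beta power is zero; ratio 1 undefined",
           class = "tmsreact_undefined_ratio")
  tibble(channel = wide$channel, ratio1 = (wide$delta + wide$theta) / denom)
}

#' Region-averaged spectral metric
#'
#' Unweighted mean of a per-channel metric over a montage cluster.
#'
#' @param summary A `spectral_summary`.
#' @param cluster Cluster name defined in the montage (e.g. `"frontal"`).
#' @param band Band name, for `metric` `"rel_power"` / `"abs_power"`; ignored
#'   for `"ratio1"`.
#' @param metric One of `"rel_power"`, `"abs_power"`, `"ratio1"`.
#' @param montage Montage holding the cluster; defaults to the recording's.
#'
#' @return A single numeric value.
#' @export
#' @examples
#' # frontal delta relative power:
#' # region_average(summary, "frontal", band = "delta")
region_average <- function(summary, cluster, band = NULL,
                           metric = c("rel_power", "abs_power", "ratio1"),
                           montage = NULL) {
  metric <- match.arg(metric)
  montage <- montage %||% summary$psd$montage
  ch <- cluster_channels(montage, cluster)
  if (metric == "ratio1") {
    r <- slow_fast_ratio(summary)
    vals <- r$ratio1[match(ch, r$channel)]
  } else {
    abort_if(is.null(band), "band is required for power metrics")
    bp <- summary$band_power
    sel <- bp$band == band & bp$channel %in% ch
    abort_if(sum(sel) != length(ch), "cluster channels missing from summary",
             class = "tmsreact_lookup_error")
    vals <- bp[[metric]][sel]
  }
  mean(vals)
}

#' One-call resting spectral summary
#'
#' Convenience wrapper: Welch PSD, band powers, and the slowing ratio.
#'
#' @inheritParams welch_psd
#' @inheritParams relative_band_power
#' @return A `spectral_summary` whose `ratio1` element holds the per-channel
#'   slowing ratio tibble.
#' @export
resting_spectral <- function(rec, bands = eeg_bands(), segment_seconds = 2,
                             overlap_fraction = 0.5, total_range = c(1, 45)) {
  s <- relative_band_power(welch_psd(rec, segment_seconds, overlap_fraction),
                           bands, total_range)
  s$ratio1 <- slow_fast_ratio(s)
  s
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> ", length(x$total_power), " channels, ",
      nrow(x$bands), " bands; total range ", x$total_range[1], "-",
      x$total_range[2], " Hz\n", sep = "")
  invisible(x)
}
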