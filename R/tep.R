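#' TMS-evoked potential epochs
#'
#' Container for TMS-locked EEG: a trials x channels x time array in
#' microvolts on a millisecond time axis spanning -1000..1000 ms around the
#' pulse (t = 0 at pulse onset).
#'
#' @param data Numeric array, trials x channels x time.
#' @param times Time axis in ms; must include 0.
#' @param fs Sampling rate in Hz.
#' @param montage An [eeg_montage()].
#' @param stim_side Stimulated hemisphere, `"left"` or `"right"` (optional).
#' @param stim_role `"M1plus"` or `"M1minus"` (optional).
#'
#' @return An object of class `tep_epochs`.
#' @export
tep_epochs <- function(data, times, fs, montage, stim_side = NULL,
                       stim_role = NULL) {
  abort_if(length(dim(data)) != 3L, "data must be trials x channels x time")
  abort_if(dim(data)[1] < 1L, "need at least one trial")
  abort_if(dim(data)[2] != length(montage$names),
           "channel dimension must match the montage")
  abort_if(dim(data)[3] != length(times), "time dimension must match times")
  abort_if(!any(times == 0), "time axis must include t = 0 (the pulse)")
  structure(list(data = data, times = times, fs = fs, montage = montage,
                 stim_side = stim_side, stim_role = stim_role,
                 interpolated_window = NULL, rejected_trials = integer(0),
                 dropped_events = 0L),
            class = "tep_epochs")
}

#' @export
print.tep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<tep_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples (", min(x$times), "..", max(x$times), " ms)\n", sep = "")
  if (!is.null(x$interpolated_window))
    cat("  interpolated window: ", x$interpolated_window[1], "..",
        x$interpolated_window[2], " ms\n", sep = "")
  if (length(x$rejected_trials))
    cat("  rejected trials: ", length(x$rejected_trials), "\n", sep = "")
  invisible(x)
}

#' Cut continuous EEG into pulse-locked epochs
#'
#' One epoch per event, spanning `window` (default -1000..1000 ms) around the
#' pulse; the sample at t = 0 is the sample at the pulse time. Events without
#' full window support inside the recording are dropped with a warning and
#' counted in `dropped_events`.
#'
#' @param raw An [eeg_recording()] containing the TMS session.
#' @param events Pulse onset times in seconds from recording start.
#' @param window Epoch window in ms, `c(start, end)`.
#' @inheritParams tep_epochs
#' @return A [tep_epochs()] object.
#' @export
epoch_tms <- function(raw, events, window = c(-1000, 1000),
                      stim_side = NULL, stim_role = NULL) {
  abort_if(!inherits(raw, "eeg_recording"), "raw must be an eeg_recording")
  step_ms <- 1000 / raw$fs
  times <- seq(window[1], window[2], by = step_ms)
  rel_idx <- round(times * raw$fs / 1000)
  ev_idx <- round(events * raw$fs) + 1L
  ok <- ev_idx + min(rel_idx) >= 1L & ev_idx + max(rel_idx) <= n_samples(raw)
  dropped <- sum(!ok)
  if (dropped > 0) {
    warn(paste0(dropped, " event(s) too close to the record edge; dropped"))
  }
  abort_if(!any(ok), "no event has full epoch support in the recording")
  ev_idx <- ev_idx[ok]
  nch <- nrow(raw$data)
  out <- array(0, c(length(ev_idx), nch, length(times)))
  for (tr in seq_along(ev_idx)) {
    out[tr, , ] <- raw$data[, ev_idx[tr] + rel_idx, drop = FALSE]
  }
  ep <- tep_epochs(out, times, raw$fs, raw$montage, stim_side, stim_role)
  ep$dropped_events <- dropped
  ep
}

#' Interpolate the pulse-artifact window
#'
#' Replaces samples strictly inside `window` (default -5..15 ms, the magnetic
#' pulse artifact) with a cubic polynomial fitted to 5 anchor samples on each
#' side of the window; every sample outside the window is bit-identical to
#' the input.
#'
#' @param epochs A [tep_epochs()] object.
#' @param window Artifact window in ms.
#' @param n_anchor Anchor samples on each side (default 5).
#' @return The epochs with the window interpolated and
#'   `interpolated_window` recorded.
#' @export
interpolate_artifact <- function(epochs, window = c(-5, 15), n_anchor = 5L) {
  abort_if(!inherits(epochs, "tep_epochs"), "epochs must be tep_epochs")
  t <- epochs$times
  abort_if(window[1] >= window[2], "window must be ordered")
  inside <- which(t > window[1] & t < window[2])
  abort_if(length(inside) == 0, "window contains no samples")
  abort_if(length(inside) >= length(t) - 2L * n_anchor,
           "window covers (nearly) the whole epoch")
  left <- (min(inside) - n_anchor):(min(inside) - 1L)
  right <- (max(inside) + 1L):(max(inside) + n_anchor)
  abort_if(min(left) < 1L || max(right) > length(t),
           "not enough anchor samples around the window")
  anchors <- c(left, right)
  # cubic least-squares fit on the anchors, evaluated inside the window
  tc <- (t - mean(t[anchors])) / 100          # centred/scaled for conditioning
  basis <- cbind(1, tc, tc^2, tc^3)
  Xa <- basis[anchors, , drop = FALSE]
  Xi <- basis[inside, , drop = FALSE]
  proj <- Xi %*% solve(crossprod(Xa), t(Xa))
  d <- epochs$data
  for (tr in seq_len(dim(d)[1])) {
    d[tr, , inside] <- d[tr, , anchors, drop = FALSE][1, , ] %*% t(proj)
  }
  epochs$data <- d
  epochs$interpolated_window <- window
  epochs
}

#' Reject trials on absolute amplitude
#'
#' Removes trials whose absolute amplitude exceeds `abs_threshold` on any
#' channel at any time outside the excluded window (by default the
#' interpolated pulse-artifact window). A threshold-based rejection stands in
#' for manual/ICA-based cleaning when processing simulated or pre-cleaned
#' data.
#'
#' @param epochs A [tep_epochs()] object.
#' @param abs_threshold Rejection threshold in microvolts (default 100).
#' @param exclude_window Window in ms ignored by the threshold; defaults to
#'   the recorded interpolated window, or nothing.
#' @return The epochs with offending trials removed and listed in
#'   `rejected_trials`.
#' @export
reject_epochs <- function(epochs, abs_threshold = 100,
                          exclude_window = NULL) {
  abort_if(!inherits(epochs, "tep_epochs"), "epochs must be tep_epochs")
  abort_if(abs_threshold <= 0, "threshold must be positive")
  exclude_window <- exclude_window %||% epochs$interpolated_window
  keep_t <- rep(TRUE, length(epochs$times))
  if (!is.null(exclude_window)) {
    keep_t <- !(epochs$times > exclude_window[1] &
                  epochs$times < exclude_window[2])
  }
  peak <- apply(abs(epochs$data[, , keep_t, drop = FALSE]), 1L, max)
  bad <- which(peak > abs_threshold)
  abort_if(length(bad) == dim(epochs$data)[1],
           paste0("all trials exceed the ", abs_threshold,
                  " microvolt rejection threshold"),
           class = "tmsreact_pipeline_error")
  if (length(bad)) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
  }
  epochs$rejected_trials <- bad
  epochs
}

#' Average epochs into an evoked response
#'
#' Per-channel mean across retained trials, followed by subtraction of each
#' channel's mean over the baseline window (default -500..-50 ms, ending
#' before any pre-pulse filter ringing).
#'
#' @param epochs A [tep_epochs()] object.
#' @param baseline Baseline window in ms.
#' @return An object of class `evoked`: list with `data` (channels x time),
#'   `times`, `montage`, `n_trials`, `baseline`.
#' @export
average_tep <- function(epochs, baseline = c(-500, -50)) {
  abort_if(!inherits(epochs, "tep_epochs"), "epochs must be tep_epochs")
  abort_if(dim(epochs$data)[1] < 1L, "no retained trials")
  m <- apply(epochs$data, c(2L, 3L), mean)
  if (!is.null(baseline)) {
    bl <- epochs$times >= baseline[1] & epochs$times <= baseline[2]
    abort_if(!any(bl), "baseline window contains no samples")
    m <- m - rowMeans(m[, bl, drop = FALSE])
  }
  rownames(m) <- epochs$montage$names
  structure(list(data = m, times = epochs$times, montage = epochs$montage,
                 n_trials = dim(epochs$data)[1], baseline = baseline,
                 stim_side = epochs$stim_side, stim_role = epochs$stim_role),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat("<evoked> ", nrow(x$data), " channels, ", x$n_trials,
      " trials averaged\n", sep = "")
  invisible(x)
}

evoked_trace <- function(kind, times, values, n_trials, baseline,
                         cluster = NULL) {
  structure(list(kind = kind, times = times, values = values,
                 n_trials = n_trials, baseline = baseline, cluster = cluster),
            class = "evoked_trace")
}

#' @export
print.evoked_trace <- function(x, ...) {
  cat("<evoked_trace> ", x$kind,
      if (!is.null(x$cluster)) paste0(" (", x$cluster, ")"), ", ",
      length(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Global mean field amplitude
#'
#' GMFA(t) is the standard deviation of the evoked voltage across the K
#' electrodes at each time point:
#' \deqn{GMFA(t) = \sqrt{\sum_i^K (V_i(t) - \bar V(t))^2 / K}}
#' It is reference-free (invariant to adding a common offset to all
#' channels) and scales by |c| when the data are scaled by c.
#'
#' @param evoked An `evoked` object from [average_tep()].
#' @return An `evoked_trace` of kind `"gmfa"` (values >= 0).
#' @export
gmfa <- function(evoked) {
  abort_if(!inherits(evoked, "evoked"), "evoked must come from average_tep()")
  abort_if(nrow(evoked$data) < 2L, "GMFA requires at least 2 channels")
  centred <- sweep(evoked$data, 2L, colMeans(evoked$data))
  vals <- sqrt(colMeans(centred^2))
  evoked_trace("gmfa", evoked$times, vals, evoked$n_trials, evoked$baseline)
}

#' Local TEP over an electrode cluster
#'
#' Unweighted mean of the evoked response across the channels of a montage
#' cluster - for M1 stimulation, the nine electrodes nearest the coil
#' (`"m1_left"` / `"m1_right"`).
#'
#' @param evoked An `evoked` object.
#' @param cluster Cluster name in the montage.
#' @param montage Montage holding the cluster (defaults to the evoked's).
#' @return An `evoked_trace` of kind `"local"`.
#' @export
local_tep <- function(evoked, cluster, montage = NULL) {
  abort_if(!inherits(evoked, "evoked"), "evoked must come from average_tep()")
  montage <- montage %||% evoked$montage
  ch <- cluster_channels(montage, cluster)
  idx <- montage_index(evoked$montage, ch)
  vals <- colMeans(evoked$data[idx, , drop = FALSE])
  evoked_trace("local", evoked$times, vals, evoked$n_trials, evoked$baseline,
               cluster = cluster)
}

#' Default TEP component definitions
#'
#' Search windows for the canonical TMS-evoked components over M1, following
#' the standard TEP literature: P30 (20-40 ms), N45 (40-55), P60 (55-80),
#' N100 (85-140), P180 (150-250). Polarity +1 marks positive peaks, -1
#' troughs; on a GMFA trace all components are maxima.
#'
#' @return A tibble with columns `component`, `polarity`, `window_lo`,
#'   `window_hi` (ms).
#' @export
tep_component_windows <- function() {
  tibble(
    component = c("P30", "N45", "P60", "N100", "P180"),
    polarity = c(1, -1, 1, -1, 1),
    window_lo = c(20, 40, 55, 85, 150),
    window_hi = c(40, 55, 80, 140, 250)
  )
}

#' Extract component peaks from an evoked trace
#'
#' For each component, locates the sign-appropriate local extremum within
#' its search window: local maxima for positive components (and for every
#' component on a GMFA trace, which is nonnegative), local minima for
#' negative ones. When several qualifying extrema exist the largest
#' amplitude wins (most negative for troughs); equal amplitudes resolve to
#' the earliest latency. `found = FALSE` marks windows without any interior
#' extremum of the right polarity (e.g. a monotone trace).
#'
#' @param trace An `evoked_trace` from [gmfa()] or [local_tep()].
#' @param components Component definition tibble, see
#'   [tep_component_windows()].
#' @return A `peak_table` tibble: `component`, `polarity`, `window_lo`,
#'   `window_hi`, `latency_ms`, `amplitude`, `found`.
#' @export
extract_peaks <- function(trace, components = tep_component_windows()) {
  abort_if(!inherits(trace, "evoked_trace"),
           "trace must be an evoked_trace (gmfa() or local_tep())")
  t <- trace$times
  v <- trace$values
  abort_if(min(t) > min(components$window_lo) ||
             max(t) < max(components$window_hi),
           "trace does not span all component search windows")
  pol <- if (trace$kind == "gmfa") rep(1, nrow(components)) else
    components$polarity
  out <- components
  out$polarity <- pol
  res <- purrr::pmap(list(pol, components$window_lo, components$window_hi),
                     function(p, lo, hi) find_peak(t, v, p, lo, hi))
  out$latency_ms <- vapply(res, `[[`, numeric(1), "latency")
  out$amplitude <- vapply(res, `[[`, numeric(1), "amplitude")
  out$found <- vapply(res, `[[`, logical(1), "found")
  class(out) <- c("peak_table", class(out))
  out
}

find_peak <- function(t, v, polarity, lo, hi) {
  s <- v * polarity
  n <- length(s)
  interior <- 2L:(n - 1L)
  is_ext <- s[interior] > s[interior - 1L] & s[interior] > s[interior + 1L]
  cand <- interior[is_ext]
  cand <- cand[t[cand] >= lo & t[cand] <= hi]
  if (length(cand) == 0) {
    return(list(found = FALSE, latency = NA_real_, amplitude = NA_real_))
  }
  best <- cand[order(-s[cand], t[cand])][1]   # largest extremum, earliest tie
  list(found = TRUE, latency = t[best], amplitude = v[best])
}

#' Map the affected side to stimulation roles
#'
#' M1(+) is the primary motor cortex contralateral to the more affected
#' upper limb; M1(-) is ipsilateral. The mapping is an involution.
#'
#' @param affected_upper_limb `"left"` or `"right"`.
#' @return Named list with `M1plus` and `M1minus` hemispheres.
#' @export
#' @examples
#' map_m1_sides("right")  # M1plus = "left"
map_m1_sides <- function(affected_upper_limb) {
  abort_if(!is.character(affected_upper_limb) ||
             !affected_upper_limb[1] %in% c("left", "right"),
           "affected side must be 'left' or 'right'")
  if (affected_upper_limb[1] == "right") {
    list(M1plus = "left", M1minus = "right")
  } else {
    list(M1plus = "right", M1minus = "left")
  }
}
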