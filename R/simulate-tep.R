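#' Specification for simulated TEP epochs
#'
#' Describes a set of TMS-locked epochs as a sum of planted evoked
#' components (Gaussian bumps in time, scaled per channel by a topography),
#' a large pulse artifact confined to the artifact window, and white noise.
#' Gaussian bumps are deliberately non-physiological: they give analytic
#' ground truth for amplitude/latency recovery tests.
#'
#' @param n_trials Number of pulses (default 100).
#' @param components List of [tep_component()] entries.
#' @param artifact_window Window in ms receiving the pulse artifact
#'   (default `c(-5, 15)`).
#' @param artifact_amplitude Artifact amplitude in microvolts (default 0).
#' @param noise_sd White-noise standard deviation in microvolts.
#' @param iti_s Inter-trial interval in seconds (default 3), used when the
#'   epochs are written out as a continuous session.
#' @param fs Sampling rate in Hz (default 1000).
#' @param window Epoch window in ms (default -1000..1000).
#' @param seed Integer seed.
#'
#' @return A `tep_sim_spec` list.
#' @export
tep_sim_spec <- function(n_trials = 100, components = list(),
                         artifact_window = c(-5, 15), artifact_amplitude = 0,
                         noise_sd = 0, iti_s = 3, fs = 1000,
                         window = c(-1000, 1000), seed = 1) {
  abort_if(n_trials < 1, "n_trials must be at least 1")
  for (cmp in components) {
    abort_if(cmp$latency <= 15 || cmp$latency >= 400,
             paste0("component '", cmp$name,
                    "' latency must lie in (15, 400) ms"))
  }
  structure(list(n_trials = as.integer(n_trials), components = components,
                 artifact_window = artifact_window,
                 artifact_amplitude = artifact_amplitude,
                 noise_sd = noise_sd, iti_s = iti_s, fs = fs,
                 window = window, seed = seed),
            class = "tep_sim_spec")
}

#' @param name Component label (e.g. `"P60"`).
#' @param latency Peak latency in ms after the pulse.
#' @param amplitude Peak amplitude in microvolts (negative for troughs).
#' @param width Gaussian standard deviation in ms.
#' @param topography Per-channel scaling: a single number (uniform), a named
#'   vector over channel labels (others 0), or a full-length vector.
#' @rdname tep_sim_spec
#' @export
tep_component <- function(name, latency, amplitude, width, topography = 1) {
  list(name = name, latency = latency, amplitude = amplitude, width = width,
       topography = topography)
}

topo_vector <- function(topography, montage) {
  nch <- length(montage$names)
  if (length(topography) == 1L && is.null(names(topography))) {
    return(rep(as.numeric(topography), nch))
  }
  if (!is.null(names(topography))) {
    v <- numeric(nch)
    v[montage_index(montage, names(topography))] <- as.numeric(topography)
    return(v)
  }
  abort_if(length(topography) != nch,
           "topography must be scalar, named, or one value per channel")
  as.numeric(topography)
}

#' Simulate TEP epochs with known ground truth
#'
#' Builds an `n_trials x channels x time` array on a 1-ms grid spanning the
#' epoch window. Each planted component contributes
#' `amplitude * exp(-(t - latency)^2 / (2 width^2))` scaled by its
#' topography, identically on every trial; the pulse artifact (an
#' exponentially decaying deflection of `artifact_amplitude`) is injected
#' only strictly inside the artifact window; white noise is added per trial.
#' A component whose latency falls inside the artifact window is kept, with
#' a warning.
#'
#' @param spec A [tep_sim_spec()].
#' @param montage An [eeg_montage()].
#' @return A [tep_epochs()] object.
#' @export
#' @examples
#' spec <- tep_sim_spec(n_trials = 10,
#'                      components = list(tep_component("P60", 60, 5, 10)),
#'                      noise_sd = 0, seed = 1)
#' ep <- simulate_tep_epochs(spec, default_montage())
simulate_tep_epochs <- function(spec, montage = default_montage()) {
  abort_if(!inherits(spec, "tep_sim_spec"), "spec must be a tep_sim_spec")
  step_ms <- 1000 / spec$fs
  times <- seq(spec$window[1], spec$window[2], by = step_ms)
  nch <- length(montage$names)
  nt <- length(times)

  base <- matrix(0, nch, nt)
  for (cmp in spec$components) {
    if (cmp$latency > spec$artifact_window[1] &&
        cmp$latency < spec$artifact_window[2]) {
      warn(paste0("component '", cmp$name,
                  "' latency lies inside the artifact window; kept"))
    }
    bump <- cmp$amplitude * exp(-(times - cmp$latency)^2 / (2 * cmp$width^2))
    base <- base + outer(topo_vector(cmp$topography, montage), bump)
  }
  if (spec$artifact_amplitude != 0) {
    inside <- times > spec$artifact_window[1] & times < spec$artifact_window[2]
    art <- numeric(nt)
    art[inside] <- spec$artifact_amplitude *
      exp(-(times[inside] - spec$artifact_window[1]) / 5)
    base <- base + matrix(art, nch, nt, byrow = TRUE)
  }

  with_seed(spec$seed, {
    data <- array(0, c(spec$n_trials, nch, nt))
    for (tr in seq_len(spec$n_trials)) {
      noise <- if (spec$noise_sd > 0) {
        matrix(rnorm(nch * nt, sd = spec$noise_sd), nch, nt)
      } else 0
      data[tr, , ] <- base + noise
    }
    tep_epochs(data, times, spec$fs, montage)
  })
}

#' Render simulated epochs as a continuous TMS session
#'
#' Concatenates the epochs at the spec's inter-trial interval into one
#' continuous [eeg_recording()] plus pulse event times, for exercising
#' [epoch_tms()] and file round-trips.
#'
#' @param spec A [tep_sim_spec()].
#' @param montage An [eeg_montage()].
#' @return A list with `recording` (an `eeg_recording`) and `events`
#'   (pulse times in seconds).
#' @export
simulate_tep_session <- function(spec, montage = default_montage()) {
  ep <- simulate_tep_epochs(spec, montage)
  fs <- spec$fs
  iti <- round(spec$iti_s * fs)
  pre <- round(-spec$window[1] * fs / 1000)
  post <- round(spec$window[2] * fs / 1000)
  ns <- pre + (spec$n_trials - 1L) * iti + post + fs   # 1 s tail padding
  x <- matrix(0, length(montage$names), ns)
  onsets <- pre + (seq_len(spec$n_trials) - 1L) * iti + 1L
  for (tr in seq_len(spec$n_trials)) {
    idx <- (onsets[tr] - pre):(onsets[tr] + post)
    x[, idx] <- ep$data[tr, , ]
  }
  list(recording = eeg_recording(x, fs, montage),
       events = (onsets - 1L) / fs)
}
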