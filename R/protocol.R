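#' Stimulation protocol scheduler
#'
#' Builds the pulse-train structure of the two bilateral M1 excitatory
#' protocols and derives total pulse count and session duration from that
#' structure (never hard-coded):
#'
#' * `"iTBS"`: per hemisphere, 20 trains of 10 triplet bursts; bursts repeat
#'   at 5 Hz with the 3 pulses of a burst at 50 Hz (2 s on), with 8 s between
#'   trains. 600 pulses per side, 1200 in total.
#' * `"rTMS10"`: per hemisphere, 20 trains of 30 pulses at 10 Hz with a 40-s
#'   inter-train interval. 600 pulses per side, 1200 in total.
#'
#' @param kind `"iTBS"` or `"rTMS10"`.
#'
#' @return A `stim_protocol` list with the train structure, `total_pulses`,
#'   and `duration_s` (from the first pulse to the last, per side x sides,
#'   sides stimulated back to back).
#' @export
#' @examples
#' build_protocol("iTBS")$total_pulses
#' build_protocol("rTMS10")$total_pulses
build_protocol <- function(kind = c("iTBS", "rTMS10")) {
  abort_if(!is.character(kind) || !kind[1] %in% c("iTBS", "rTMS10"),
           "kind must be 'iTBS' or 'rTMS10'")
  kind <- match.arg(kind)
  if (kind == "iTBS") {
    p <- list(kind = kind, sides = 2L, trains_per_side = 20L,
              pulses_per_burst = 3L, bursts_per_train = 10L,
              burst_rate_hz = 5, intra_burst_rate_hz = 50,
              inter_train_interval_s = 8)
    p$pulses_per_train <- p$pulses_per_burst * p$bursts_per_train
  } else {
    p <- list(kind = kind, sides = 2L, trains_per_side = 20L,
              pulses_per_train = 30L, intra_train_rate_hz = 10,
              inter_train_interval_s = 40)
  }
  p$total_pulses <- p$sides * p$trains_per_side * p$pulses_per_train
  times <- protocol_pulse_times(p)
  p$duration_s <- max(times$time_s) - min(times$time_s)
  structure(p, class = "stim_protocol")
}

#' Scheduled pulse times of a protocol
#'
#' Enumerates every pulse of a [build_protocol()] schedule.
#'
#' @param protocol A `stim_protocol`.
#' @return A tibble with columns `side`, `train`, `pulse`, `time_s`.
#' @export
protocol_pulse_times <- function(protocol) {
  p <- protocol
  if (p$kind == "iTBS") {
    burst_gap <- 1 / p$burst_rate_hz
    pulse_gap <- 1 / p$intra_burst_rate_hz
    within_train <- as.vector(outer(
      (seq_len(p$pulses_per_burst) - 1) * pulse_gap,
      (seq_len(p$bursts_per_train) - 1) * burst_gap, `+`
    ))
    train_len <- p$bursts_per_train * burst_gap        # 2 s on
  } else {
    within_train <- (seq_len(p$pulses_per_train) - 1) / p$intra_train_rate_hz
    train_len <- p$pulses_per_train / p$intra_train_rate_hz
  }
  train_starts <- (seq_len(p$trains_per_side) - 1) *
    (train_len + p$inter_train_interval_s)
  side_len <- max(train_starts) + max(within_train) + p$inter_train_interval_s
  out <- tidyr::expand_grid(side = seq_len(p$sides),
                            train = seq_len(p$trains_per_side),
                            pulse = seq_len(p$pulses_per_train))
  out$time_s <- (out$side - 1) * side_len +
    train_starts[out$train] + within_train[out$pulse]
  out
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol> ", x$kind, ": ", x$sides, " sides x ",
      x$trains_per_side, " trains x ", x$pulses_per_train,
      " pulses = ", x$total_pulses, " pulses; ~",
      round(x$duration_s), " s\n", sep = "")
  invisible(x)
}
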