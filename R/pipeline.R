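#' Pipeline configuration
#'
#' Bundles every tunable of the analysis into one validated object: band
#' set, Welch parameters, connectivity band and pair, TEP windows and
#' rejection threshold, and the output directory. Windows must be ordered
#' and every referenced channel must exist in the montage.
#'
#' @param subjects Data frame with one row per subject: `id`,
#'   `affected_side`, `rest_file` (baseline resting recording), optionally
#'   `tep_file` (M1(+) TMS session with pulse events in its sidecar), and
#'   any clinical columns to carry through.
#' @param out_dir Output directory (created if absent).
#' @param montage An [eeg_montage()].
#' @param bands A [eeg_bands()] set.
#' @param pli_band Band for the connectivity stage.
#' @param pli_pair Channel pair reported as a feature.
#' @param frontal_cluster Cluster for the frontal power feature.
#' @param segment_seconds,overlap_fraction Welch parameters.
#' @param epoch_window,artifact_window,baseline_window TEP windows in ms.
#' @param reject_threshold Trial-rejection threshold in microvolts.
#' @param components TEP component definitions
#'   ([tep_component_windows()]).
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(subjects, out_dir, montage = default_montage(),
                            bands = eeg_bands(), pli_band = "delta",
                            pli_pair = c("F2", "F7"),
                            frontal_cluster = "frontal",
                            segment_seconds = 2, overlap_fraction = 0.5,
                            epoch_window = c(-1000, 1000),
                            artifact_window = c(-5, 15),
                            baseline_window = c(-500, -50),
                            reject_threshold = 100,
                            components = tep_component_windows(),
                            seed = 1) {
  for (w in list(epoch_window, artifact_window, baseline_window)) {
    abort_if(w[1] >= w[2], "every window must be ordered (start < end)")
  }
  montage_index(montage, pli_pair)
  cluster_channels(montage, frontal_cluster)
  abort_if(!all(c("id", "affected_side", "rest_file") %in% names(subjects)),
           "subjects needs id, affected_side, rest_file columns")
  structure(list(subjects = subjects, out_dir = out_dir, montage = montage,
                 bands = bands, pli_band = pli_band, pli_pair = pli_pair,
                 frontal_cluster = frontal_cluster,
                 segment_seconds = segment_seconds,
                 overlap_fraction = overlap_fraction,
                 epoch_window = epoch_window,
                 artifact_window = artifact_window,
                 baseline_window = baseline_window,
                 reject_threshold = reject_threshold,
                 components = components, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' For each subject: read the baseline resting recording, compute the
#' spectral summary (frontal delta relative power, slowing ratio) and the
#' delta-band PLI feature; if a TMS session file is present, epoch around
#' the pulses, interpolate the artifact window, reject out-of-range trials,
#' average, and quantify GMFA and local M1(+) component peaks. Writes
#' long-format `features.csv` (subject, stage, metric, value), `peaks.csv`,
#' and a `manifest.json` with the configuration echo, seed, every input
#' file consumed, and per-subject epoch counts. A subject whose TMS file is
#' missing gets the resting outputs only, with a log entry; errors abort
#' with the stage and subject id.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `features` (tibble), `peaks` (tibble),
#'   and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  abort_if(!inherits(config, "pipeline_config"),
           "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (!quiet) message(...)

  features <- list()
  peaks <- list()
  consumed <- character(0)
  counts <- list()

  for (i in seq_len(nrow(config$subjects))) {
    s <- config$subjects[i, ]
    stage <- "rest"
    res <- tryCatch({
      rec <- read_recording(s$rest_file, config$montage)
      consumed <- c(consumed, s$rest_file)
      spec <- resting_spectral(rec, config$bands, config$segment_seconds,
                               config$overlap_fraction)
      pli <- connectivity_matrix(rec, config$pli_band, config$bands)
      feat <- extract_features(spec, pli, config$frontal_cluster,
                               config$pli_pair)
      ratio <- mean(spec$ratio1$ratio1)
      log_line("[rest] ", s$id, ": frontal delta relpow ",
               round(feat$frontal_delta_relpow, 3))
      features[[length(features) + 1L]] <- tibble(
        subject = s$id, stage = "rest",
        metric = c("frontal_delta_relpow", "f2f7_delta_pli", "ratio1"),
        value = c(feat$frontal_delta_relpow, feat$f2f7_delta_pli, ratio)
      )

      if ("tep_file" %in% names(s) && !is.na(s$tep_file) &&
          nzchar(s$tep_file)) {
        stage <- "tep"
        rec_t <- read_recording(s$tep_file, config$montage)
        consumed <- c(consumed, s$tep_file)
        events <- attr(rec_t, "events")
        abort_if(is.null(events), "TMS session sidecar carries no events")
        roles <- map_m1_sides(s$affected_side)
        ep <- epoch_tms(rec_t, events, config$epoch_window,
                        stim_side = roles$M1plus, stim_role = "M1plus")
        ep <- interpolate_artifact(ep, config$artifact_window)
        ep <- reject_epochs(ep, config$reject_threshold)
        ev <- average_tep(ep, config$baseline_window)
        counts[[s$id]] <- list(epochs_kept = dim(ep$data)[1],
                               epochs_rejected = length(ep$rejected_trials))
        log_line("[tep] ", s$id, ": ", dim(ep$data)[1], " epochs kept, ",
                 length(ep$rejected_trials), " rejected")
        cl <- paste0("m1_", roles$M1plus)
        for (tr in list(gmfa(ev), local_tep(ev, cl))) {
          pk <- extract_peaks(tr, config$components)
          pk$subject <- s$id
          pk$trace <- tr$kind
          peaks[[length(peaks) + 1L]] <- pk
        }
      } else {
        log_line("[tep] ", s$id, ": no TMS session file; stage skipped")
      }
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      abort(paste0("pipeline failed at stage '", stage, "' for subject ",
                   s$id, ": ", conditionMessage(res)),
            class = "tmsreact_pipeline_error")
    }
  }

  features <- dplyr::bind_rows(features)
  peaks <- if (length(peaks)) dplyr::bind_rows(peaks) else tibble()
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(peaks, file.path(config$out_dir, "peaks.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    inputs = unique(consumed),
    subjects = config$subjects$id,
    epoch_counts = counts,
    settings = config[c("pli_band", "pli_pair", "frontal_cluster",
                        "segment_seconds", "overlap_fraction",
                        "epoch_window", "artifact_window",
                        "baseline_window", "reject_threshold")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, peaks = peaks, manifest = manifest))
}
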