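#' Write and read recordings on disk
#'
#' Two interchange formats are supported:
#' * `"tsv"`: a plain tab-delimited numeric matrix (samples x channels, with
#'   a channel-label header row) plus a JSON sidecar `<path>.json` holding
#'   the sampling rate, channel order, and optional pulse event times.
#' * `"edf"`: standard 16-bit EDF via [write_edf()] / [read_edf()]; events,
#'   if any, still go to the JSON sidecar.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path; the extension (`.tsv`/`.txt` or `.edf`) selects
#'   the format.
#' @param events Optional numeric vector of pulse times in seconds.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, events = NULL) {
  abort_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    write_edf(rec, path)
  } else if (ext %in% c("tsv", "txt")) {
    m <- t(rec$data)
    colnames(m) <- rec$montage$names
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    abort(paste0("unknown recording extension '.", ext, "'"))
  }
  sidecar <- list(fs = rec$fs, channels = rec$montage$names)
  if (!is.null(events)) sidecar$events <- events
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param montage Optional [eeg_montage()]; channels are reordered to match
#'   it and a missing channel is a lookup error naming it.
#' @param expect_fs Optional sampling rate to validate against the file's
#'   (a mismatch is an error).
#' @return `read_recording()` returns an [eeg_recording()] with an
#'   `events` attribute when the sidecar carries pulse times.
#' @rdname write_recording
#' @export
read_recording <- function(path, montage = NULL, expect_fs = NULL) {
  ext <- tolower(tools::file_ext(path))
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  }
  if (ext == "edf") {
    rec <- read_edf(path, montage)
  } else if (ext %in% c("tsv", "txt")) {
    abort_if(is.null(sidecar),
             paste0("missing JSON sidecar for delimited recording: ",
                    side_path))
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
    rec <- finalize_recording(t(m), colnames(m), sidecar$fs, montage)
  } else {
    abort(paste0("unknown recording extension '.", ext, "'"))
  }
  if (!is.null(expect_fs)) {
    abort_if(rec$fs != expect_fs,
             paste0("sampling-rate mismatch: file has ", rec$fs,
                    " Hz, expected ", expect_fs, " Hz"))
  }
  if (!is.null(sidecar$events)) attr(rec, "events") <- sidecar$events
  rec
}

#' Write a cohort table as CSV
#'
#' Plain CSV with the documented [simulate_cohort()] column names.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
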