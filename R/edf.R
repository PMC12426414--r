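# Minimal EDF (European Data Format) support for continuous recordings:
# 16-bit samples, one-second data records, no annotations. Events travel in
# the JSON sidecar (see write_recording). Implemented here because the
# standard exchange format for clinical EEG is EDF and the surrounding R
# stack provides no reader/writer.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Standard EDF: 16-bit integers against a symmetric physical range chosen
#' per channel, one-second data records. The trailing partial second, if
#' any, is zero-padded (use whole-second recordings for exact round trips).
#' Quantisation error is bounded by half the physical range divided by
#' 2^15 - 1.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  abort_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  abort_if(rec$fs != round(rec$fs), "EDF writer requires an integer fs")
  x <- rec$data
  nch <- nrow(x)
  fs <- as.integer(rec$fs)
  n_rec <- as.integer(ceiling(ncol(x) / fs))
  if (ncol(x) < n_rec * fs) {
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))
  }
  pmax_ <- ceiling(apply(abs(x), 1L, max))   # integer range fits the 8-char field
  pmax_[pmax_ == 0] <- 1
  abort_if(any(pmax_ > 9999999), "amplitudes too large for the EDF writer")
  dig_max <- 32767L; dig_min <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("tmsreact recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (nch + 1L), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(nch, 4)
  )
  fld <- function(vals, width) paste(vapply(vals, edf_pad, "", width),
                                     collapse = "")
  hdr <- paste0(
    hdr,
    fld(rec$montage$names, 16), fld(rep("", nch), 80),
    fld(rep("uV", nch), 8),
    fld(-pmax_, 8), fld(pmax_, 8),
    fld(rep(dig_min, nch), 8), fld(rep(dig_max, nch), 8),
    fld(rep("", nch), 80), fld(rep(fs, nch), 8), fld(rep("", nch), 32)
  )
  writeChar(hdr, con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((x[ch, idx] + pmax_[ch]) * scale[ch]) + dig_min
      writeBin(as.integer(pmin(dig_max, pmax(dig_min, dig))), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_num <- function(raw, n, width) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- as.numeric(rawToChar(raw[((i - 1L) * width + 1L):(i * width)]))
  }
  out
}

#' Read an EDF file
#'
#' Reads a continuous 16-bit EDF recording written by [write_edf()] (or any
#' plain EDF with a uniform per-channel sampling rate).
#'
#' @param path EDF file path.
#' @param montage Optional [eeg_montage()]; when given, channels are
#'   reordered to montage order and a missing channel raises a lookup error
#'   naming it.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "raw", 256L)
  txt <- function(raw, from, len) {
    trimws(rawToChar(raw[from:(from + len - 1L)]))
  }
  n_rec <- as.integer(txt(h, 237, 8))
  dur <- as.numeric(txt(h, 245, 8))
  nch <- as.integer(txt(h, 253, 4))
  sh <- readBin(con, "raw", 256L * nch)
  labels <- vapply(seq_len(nch), function(i) {
    txt(sh, (i - 1L) * 16L + 1L, 16L)
  }, "")
  off <- nch * 16L + nch * 80L + nch * 8L
  pmin_ <- edf_num(sh[(off + 1L):(off + nch * 8L)], nch, 8L)
  pmax_ <- edf_num(sh[(off + nch * 8L + 1L):(off + nch * 16L)], nch, 8L)
  dmin <- edf_num(sh[(off + nch * 16L + 1L):(off + nch * 24L)], nch, 8L)
  dmax <- edf_num(sh[(off + nch * 24L + 1L):(off + nch * 32L)], nch, 8L)
  off2 <- off + nch * 32L + nch * 80L
  spr <- as.integer(edf_num(sh[(off2 + 1L):(off2 + nch * 8L)], nch, 8L))
  abort_if(length(unique(spr / dur)) != 1L,
           "mixed per-channel sampling rates are not supported")
  fs <- spr[1] / dur

  x <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      x[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  rownames(x) <- labels
  finalize_recording(x, labels, fs, montage)
}

# Reorder rows to montage order (erroring on missing channels), or build an
# ad hoc montage from the file's labels.
finalize_recording <- function(x, labels, fs, montage) {
  if (is.null(montage)) {
    montage <- eeg_montage(labels)
  } else {
    missing <- setdiff(montage$names, labels)
    abort_if(length(missing) > 0,
             paste0("channel(s) missing from file: ",
                    paste(missing, collapse = ", ")),
             class = "tmsreact_lookup_error")
    x <- x[match(montage$names, labels), , drop = FALSE]
  }
  eeg_recording(x, fs, montage)
}
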