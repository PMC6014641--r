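# Minimal standard EDF (16-bit) I/O.  Covers plain EDF with a fixed
# sampling rate per signal and 1-second data records, which is all the
# synthetic recordings and the preprocessing reader need.

edf_pad <- function(x, width) substr(formatC(as.character(x), width = width,
                                             flag = "-"), 1L, width)

# format a number into at most 8 header characters
edf_num8 <- function(v) {
  for (digits in 7:1) {
    s <- formatC(signif(v, digits), format = "g", digits = digits)
    if (nchar(s) <= 8) return(s)
  }
  substr(s, 1, 8)
}

#' Write an EEG record to an EDF file
#'
#' Standard EDF: 256-byte fixed header, 256 bytes per signal, then
#' 1-second data records of little-endian 16-bit integers.  Physical
#' ranges are taken from the data per channel, so the quantization step is
#' `(max - min) / 65535` microvolts.
#'
#' @param eeg an [eeg_record()] with an integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_record"))
  fs <- as.integer(eeg$fs)
  n_rec <- nrow(eeg$samples) %/% fs
  ns <- ncol(eeg$samples)
  x <- eeg$samples[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44), edf_pad(n_rec, 8),
    edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  fld(eeg$channel_labels, 16)              # label
  fld(rep("", ns), 80)                     # transducer
  fld(rep("uV", ns), 8)                    # physical dimension
  # pad outward by 0.1% of the range before rounding to 8 header chars,
  # so the written range always covers the data
  pad <- (pmax_ - pmin_) * 1e-3
  pmin_ <- as.numeric(vapply(pmin_ - pad, edf_num8, ""))
  pmax_ <- as.numeric(vapply(pmax_ + pad, edf_num8, ""))
  fld(vapply(pmin_, edf_num8, ""), 8)
  fld(vapply(pmax_, edf_num8, ""), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)                     # prefiltering
  fld(rep(fs, ns), 8)                      # samples per record
  fld(rep("", ns), 32)                     # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (c_ in seq_len(ns)) {
      dig <- as.integer(round((x[rows, c_] - pmin_[c_]) / scale[c_]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' Reads plain 16-bit EDF with a constant per-signal sampling rate,
#' rescaling digital values to physical units from the header ranges.
#'
#' @param path EDF file path.
#' @return an [eeg_record()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                     # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)
  rd(8 * ns)                                # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates not supported", call. = FALSE)
  fs <- spr[1] / rec_dur
  out <- matrix(NA_real_, n_rec * spr[1], ns)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (c_ in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[c_], size = 2, signed = TRUE,
                     endian = "little")
      out[rows, c_] <- pmin_[c_] + (dig - dmin[c_]) * scale[c_]
    }
  }
  eeg_record(out, fs = fs, channel_labels = labels)
}

#' Write the BP, intervention and clinical side files of a recording
#'
#' CSV for the 1 Hz systolic/diastolic series (`time_s`, `sp_mmHg`,
#' `dp_mmHg`) and a plain-text intervention list (one epoch-second per
#' line).
#'
#' @param rec a [gen_synthetic_recording()] result.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"recording"`).
#' @return named character vector of the written paths, invisibly.
#' @export
write_recording_sidecars <- function(rec, dir, stem = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bp_path <- file.path(dir, paste0(stem, "_bp.csv"))
  write.csv(rec$bp, bp_path, row.names = FALSE)
  iv_path <- file.path(dir, paste0(stem, "_interventions.txt"))
  writeLines(as.character(rec$interventions), iv_path)
  invisible(c(bp = bp_path, interventions = iv_path))
}
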