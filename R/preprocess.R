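#' Multichannel EEG container
#'
#' @param samples numeric matrix (n x 8) of per-channel samples in microvolts.
#' @param fs sampling frequency in Hz.
#' @param channel_labels eight bipolar channel names.
#' @param start_time recording start offset in seconds.
#' @return object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, channel_labels = BIPOLAR_CHANNELS,
                       start_time = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 8L) stop("exactly 8 channels required", call. = FALSE)
  if (length(channel_labels) != 8L)
    stop("exactly 8 channel labels required", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 start_time = start_time),
            class = "eeg_record")
}

#' Band-pass filter and downsample EEG to 64 Hz
#'
#' Zero-phase 4th-order Butterworth band-pass, 0.3-30 Hz, applied before
#' decimation; 256 Hz input is decimated by 4 and 1024 Hz by 16.  The 30 Hz
#' upper edge sits below the 32 Hz output Nyquist, so the band-pass also
#' serves as the anti-alias filter.
#'
#' @param eeg an [eeg_record()] at 256 or 1024 Hz.
#' @param band filter band in Hz (default `c(0.3, 30)`).
#' @return an [eeg_record()] at 64 Hz.
#' @export
filter_and_downsample <- function(eeg, band = c(0.3, 30)) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (!eeg$fs %in% c(256, 1024))
    stop("unsupported sampling rate: ", eeg$fs, call. = FALSE)
  dec <- eeg$fs / 64
  bf <- signal::butter(4, band / (eeg$fs / 2), type = "pass")
  filt <- apply(eeg$samples, 2, function(ch)
    signal::filtfilt(bf, ch))
  idx <- seq(1L, nrow(filt), by = dec)
  eeg_record(filt[idx, , drop = FALSE], fs = 64,
             channel_labels = eeg$channel_labels,
             start_time = eeg$start_time)
}

#' Mark EEG artifact seconds per channel
#'
#' Amplitude-based thresholding removing zero-signal and high-amplitude
#' artifact: a second of a channel is invalid if its peak absolute
#' amplitude exceeds `amp_thresh_uV` (electrode movement, disconnection) or
#' its peak-to-peak range falls below `flat_thresh_uV` (flat line / lost
#' signal).
#'
#' @param eeg an [eeg_record()].
#' @param amp_thresh_uV high-amplitude threshold in microvolts (default 250).
#' @param flat_thresh_uV flat-line range threshold in microvolts
#'   (default 0.1).
#' @return logical matrix (seconds x 8), TRUE where valid.
#' @export
mark_eeg_artifacts <- function(eeg, amp_thresh_uV = 250,
                               flat_thresh_uV = 0.1) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (amp_thresh_uV <= 0 || flat_thresh_uV <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  fs <- eeg$fs
  n_sec <- nrow(eeg$samples) %/% fs
  sec <- rep(seq_len(n_sec), each = fs)
  valid <- vapply(seq_len(8L), function(c_) {
    ch <- eeg$samples[seq_len(n_sec * fs), c_]
    peak <- tapply(abs(ch), sec, max)
    rng <- tapply(ch, sec, function(v) max(v) - min(v))
    peak <= amp_thresh_uV & rng >= flat_thresh_uV
  }, logical(n_sec))
  unname(valid)
}

# One-sided Hann-windowed periodogram power (density, uV^2/Hz) of an epoch
# matrix (samples x epochs); returns matrix (freq bins x epochs) and bin
# frequencies.
epoch_psd <- function(mat, fs) {
  nfft <- nrow(mat)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nfft - 1) / (nfft - 1)))
  mat <- (mat - rep(colMeans(mat), each = nfft)) * w
  sp <- Mod(stats::mvfft(mat))^2 / (fs * sum(w^2))
  half <- nfft %/% 2L
  psd <- sp[1:(half + 1L), , drop = FALSE]
  psd[2:half, ] <- 2 * psd[2:half, ]      # fold negative frequencies
  list(f = (0:half) * fs / nfft, psd = psd)
}

#' Extract 1 Hz EEG sub-band power features
#'
#' Segments the 64 Hz EEG into 60-second epochs with a 1-second shift.
#' Each epoch of each channel is Hann-windowed and transformed with the
#' DFT; the power spectral density is integrated over the four sub-bands
#' 0.3-3, 3-8, 8-15 and 15-30 Hz (half-open bins `[f1, f2)`, last band
#' closed at 30 Hz).  The per-band feature is the median across the eight
#' channels, which suppresses focal artifacts; channels with any invalid
#' second inside the epoch are excluded from the median, and epochs with
#' fewer than 4 valid channels are marked invalid.
#'
#' @param eeg64 an [eeg_record()] at 64 Hz.
#' @param valid_sec optional logical matrix (seconds x 8) from
#'   [mark_eeg_artifacts()]; default all valid.
#' @param epoch_s epoch length in seconds (default 60).
#' @param shift_s epoch shift in seconds (default 1).
#' @param bands list of band edges (Hz); default the four analysis bands.
#' @return list of class `feature_series`: `time_s` (epoch start seconds),
#'   `band_power` (epochs x 4 matrix, uV^2), `valid` (logical).
#' @export
extract_band_power <- function(eeg64, valid_sec = NULL, epoch_s = 60L,
                               shift_s = 1L, bands = EEG_BANDS) {
  stopifnot(inherits(eeg64, "eeg_record"))
  if (eeg64$fs != 64) stop("expected 64 Hz input", call. = FALSE)
  fs <- 64L
  n_sec <- nrow(eeg64$samples) %/% fs
  if (n_sec < epoch_s) stop("record shorter than one epoch", call. = FALSE)
  if (is.null(valid_sec)) valid_sec <- matrix(TRUE, n_sec, 8L)
  n_ep <- n_sec - epoch_s + 1L
  starts <- seq(1L, n_ep, by = shift_s)
  nfft <- epoch_s * fs
  # per-channel epoch validity: all epoch seconds valid on that channel
  ch_ok <- vapply(seq_len(8L), function(c_) {
    cs <- cumsum(c(0L, as.integer(valid_sec[, c_])))
    (cs[starts + epoch_s] - cs[starts]) == epoch_s
  }, logical(length(starts)))
  ch_ok <- matrix(ch_ok, nrow = length(starts))

  bp <- array(NA_real_, c(length(starts), 4L, 8L))
  chunk <- 512L
  for (c_ in seq_len(8L)) {
    ch <- eeg64$samples[, c_]
    for (b0 in seq(1L, length(starts), by = chunk)) {
      b1 <- min(b0 + chunk - 1L, length(starts))
      sub <- starts[b0:b1]
      mat <- vapply(sub, function(s) {
        i0 <- (s - 1L) * fs
        ch[(i0 + 1L):(i0 + nfft)]
      }, numeric(nfft))
      ps <- epoch_psd(matrix(mat, nrow = nfft), fs)
      df <- fs / nfft
      for (b in seq_along(bands)) {
        f1 <- bands[[b]][1]; f2 <- bands[[b]][2]
        sel <- if (b == length(bands)) ps$f >= f1 & ps$f <= f2
               else ps$f >= f1 & ps$f < f2
        bp[b0:b1, b, c_] <- colSums(ps$psd[sel, , drop = FALSE]) * df
      }
    }
  }
  out <- matrix(NA_real_, length(starts), 4L)
  n_ok <- rowSums(ch_ok)
  for (i in seq_along(starts)) {
    if (n_ok[i] < 4L) next
    for (b in 1:4) out[i, b] <- median(bp[i, b, ch_ok[i, ]])
  }
  structure(list(time_s = as.integer(starts - 1L) + eeg64$start_time,
                 band_power = out, valid = n_ok >= 4L),
            class = "feature_series")
}

#' Compute MAP from systolic and diastolic pressure
#'
#' `MAP = DP + (SP - DP) / 3`, the standard clinical formula.  Seconds with
#' the physiologically impossible `SP < DP` are marked invalid.
#'
#' @param time_s 1 Hz time grid (seconds).
#' @param sp,dp systolic / diastolic pressure (mmHg) at 1 Hz.
#' @return object of class `bp_record`: `time_s`, `sp`, `dp`, `map`,
#'   `valid`.
#' @export
compute_map <- function(time_s, sp, dp) {
  stopifnot(length(sp) == length(time_s), length(dp) == length(time_s))
  valid <- !is.na(sp) & !is.na(dp) & sp >= dp
  map <- dp + (sp - dp) / 3
  map[!valid] <- NA_real_
  structure(list(time_s = as.integer(time_s), sp = sp, dp = dp, map = map,
                 valid = valid),
            class = "bp_record")
}

#' Clean the MAP series
#'
#' Invalidates (i) seconds with MAP below `min_mmHg` (transducer
#' disconnection), (ii) outliers within each non-overlapping 1-hour block,
#' defined as `|map - median| > 3 IQR` of the block, and (iii) the 10
#' minutes before and after each clinical intervention time.
#'
#' @param bp a [compute_map()] record.
#' @param interventions numeric vector of intervention times (seconds).
#' @param min_mmHg dropout threshold (default 10).
#' @param block_s outlier block length (default 3600).
#' @param iqr_mult outlier multiplier (default 3).
#' @param guard_s seconds ignored on each side of an intervention
#'   (default 600).
#' @return the record with its mask updated and a `report` attribute
#'   counting seconds removed per rule.
#' @export
clean_bp <- function(bp, interventions = numeric(0), min_mmHg = 10,
                     block_s = 3600L, iqr_mult = 3, guard_s = 600L) {
  stopifnot(inherits(bp, "bp_record"))
  valid <- bp$valid
  low <- valid & bp$map < min_mmHg
  valid[low] <- FALSE
  out <- logical(length(valid))
  blocks <- split(seq_along(valid), (bp$time_s - bp$time_s[1]) %/% block_s)
  for (idx in blocks) {
    v <- idx[valid[idx]]
    if (length(v) < 10L) next
    m <- median(bp$map[v]); iq <- stats::IQR(bp$map[v])
    # iq = 0 (a constant block) still flags any deviating value
    bad <- v[abs(bp$map[v] - m) > iqr_mult * iq]
    out[bad] <- TRUE
  }
  valid[out] <- FALSE
  interv <- logical(length(valid))
  for (t0 in interventions)
    interv[bp$time_s >= t0 - guard_s & bp$time_s <= t0 + guard_s] <- TRUE
  removed_interv <- valid & interv
  valid[interv] <- FALSE
  bp$valid <- valid
  bp$map[!valid] <- NA_real_
  attr(bp, "report") <- list(low_bp = sum(low), outlier = sum(out),
                             intervention = sum(removed_interv))
  bp
}

#' Synchronize MAP with the EEG feature series
#'
#' Smooths MAP with the same 60-second moving average / 1-second shift used
#' for the EEG epochs (a MAP value at epoch start `t` averages seconds
#' `t .. t+59`), restricts both series to their common 1 Hz grid, and
#' intersects the validity masks so a second ignored in either source is
#' ignored in both.
#'
#' @param features a [extract_band_power()] feature series.
#' @param bp a cleaned [compute_map()] record.
#' @param epoch_s,shift_s moving-average length and shift (default 60, 1).
#' @return an [aligned_pair()].
#' @export
synchronize <- function(features, bp, epoch_s = 60L, shift_s = 1L) {
  stopifnot(inherits(features, "feature_series"), inherits(bp, "bp_record"))
  n_sec <- length(bp$time_s)
  if (n_sec < epoch_s) stop("BP record shorter than one epoch", call. = FALSE)
  starts <- seq(1L, n_sec - epoch_s + 1L, by = shift_s)
  mapv <- bp$map
  map_sm <- vapply(starts, function(s) {
    v <- mapv[s:(s + epoch_s - 1L)]
    if (anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
  ok_bp <- vapply(starts, function(s)
    all(bp$valid[s:(s + epoch_s - 1L)]), logical(1))
  t_bp <- bp$time_s[starts]
  common <- intersect(features$time_s, t_bp)
  if (length(common) == 0L) stop("no overlapping time support", call. = FALSE)
  fi <- match(common, features$time_s)
  bi <- match(common, t_bp)
  valid <- features$valid[fi] & ok_bp[bi] & !is.na(map_sm[bi])
  aligned_pair(common, map_sm[bi], features$band_power[fi, , drop = FALSE],
               valid)
}

#' Read a preprocessing configuration from YAML
#'
#' Recognized keys: `band_edges` (list of 2-vectors, Hz), `epoch_s`,
#' `shift_s`, `amp_thresh_uV`, `flat_thresh_uV`, `min_mmHg`, `iqr_mult`.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return named list of preprocessing parameters.
#' @export
preprocess_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(band_edges = EEG_BANDS, epoch_s = 60L, shift_s = 1L,
                   amp_thresh_uV = 250, flat_thresh_uV = 0.1,
                   min_mmHg = 10, iqr_mult = 3)
  utils::modifyList(defaults, cfg[intersect(names(cfg), names(defaults))])
}
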