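# Smoothed Ornstein-Uhlenbeck process sampled at `fs` Hz: mean-reverting
# Gaussian noise passed through a moving average so essentially all
# spectral power sits well below 0.5 Hz (slow MAP-like dynamics).
slow_process <- function(n, fs = 1, mean = 0, sd = 1, tau_s = 20,
                         smooth_s = 15) {
  theta <- 1 / (tau_s * fs)
  w_sd <- sqrt(2 * theta)                 # unit stationary variance
  z <- numeric(n + 10 * smooth_s * fs)
  e <- rnorm(length(z))
  for (t in 2:length(z))
    z[t] <- z[t - 1] * (1 - theta) + w_sd * e[t]
  k <- max(1L, as.integer(smooth_s * fs))
  z <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 2))
  z <- z[!is.na(z)][seq_len(n)]
  mean + sd * (z - mean(z)) / sd(z)
}

band_limited_noise <- function(n, fs, f_lo, f_hi) {
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, rnorm(n + 2 * fs)))[(fs + 1):(fs + n)]
}

#' Generate a synthetic EEG / blood-pressure recording
#'
#' Emulates the statistical structure the pipeline assumes: 8-channel EEG
#' at 256 Hz whose power is concentrated in the 0.3-3 Hz band, a slowly
#' varying MAP process (mean 35 mmHg, sd 4 mmHg, all dynamics well below
#' 0.5 Hz) output as 1 Hz systolic/diastolic pairs, and a tunable coupling
#' between the EEG delta-band amplitude envelope and the MAP process.
#' With `direction = "map_to_eeg"` the MAP fluctuations modulate the delta
#' envelope; with `"eeg_to_map"` an autonomous slow envelope drives MAP;
#' `"none"` leaves them independent.  Optionally injects the artifact
#' types the cleaning stage must remove: flat-line EEG epochs,
#' high-amplitude EEG bursts, sub-10 mmHg BP dropouts, and intervention
#' spikes with their times listed.
#'
#' @param duration_h recording duration in hours.
#' @param coupling coupling strength in \[0, 1\].
#' @param direction `"map_to_eeg"`, `"eeg_to_map"` or `"none"`.
#' @param seed integer seed.
#' @param fs EEG sampling rate (default 256).
#' @param artifacts inject artifacts? (default TRUE).
#' @param lag_s coupling lag in seconds (default 15).
#' @return list: `eeg` ([eeg_record()]), `bp` (data.frame `time_s`,
#'   `sp_mmHg`, `dp_mmHg`), `interventions` (seconds), and `truth` (ground
#'   truth: artifact seconds per type, the latent envelope and MAP).
#' @export
gen_synthetic_recording <- function(duration_h, coupling = 0.8,
                                    direction = c("map_to_eeg",
                                                  "eeg_to_map", "none"),
                                    seed = 1L, fs = 256L, artifacts = TRUE,
                                    lag_s = 15L) {
  direction <- match.arg(direction)
  if (duration_h <= 0) stop("duration_h must be > 0", call. = FALSE)
  if (coupling < 0 || coupling > 1)
    stop("coupling must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  n_sec <- as.integer(round(duration_h * 3600))
  n_eeg <- n_sec * fs

  # latent slow drivers at 1 Hz (unit variance)
  z_auto <- slow_process(n_sec + lag_s)      # autonomous envelope driver
  z_ou <- slow_process(n_sec + lag_s)        # independent MAP innovations
  if (direction == "map_to_eeg") {
    z_map <- z_ou
    z_env <- coupling * c(z_map[(lag_s + 1):(n_sec + lag_s)]) +
      sqrt(max(0, 1 - coupling^2)) * z_auto[seq_len(n_sec)]
    z_map <- z_map[seq_len(n_sec)]
  } else if (direction == "eeg_to_map") {
    z_env <- z_auto[(lag_s + 1):(n_sec + lag_s)]
    z_map <- coupling * z_auto[seq_len(n_sec)] +
      sqrt(max(0, 1 - coupling^2)) * z_ou[seq_len(n_sec)]
  } else {
    z_env <- z_auto[seq_len(n_sec)]
    z_map <- z_ou[seq_len(n_sec)]
  }

  map <- 35 + 4 * z_map
  pp <- 14 + 1.5 * slow_process(n_sec)       # pulse pressure
  sp <- map + 2 * pp / 3
  dp <- map - pp / 3

  # EEG: delta-dominated mixture; delta amplitude follows exp(z_env/2)
  env_sec <- exp(0.5 * z_env)
  env <- stats::approx(seq_len(n_sec), env_sec, n = n_eeg, rule = 2)$y
  eeg <- matrix(0, n_eeg, 8L)
  for (c_ in 1:8) {
    delta <- band_limited_noise(n_eeg, fs, 0.3, 3) * env
    rest <- 0.30 * band_limited_noise(n_eeg, fs, 3, 8) +
            0.15 * band_limited_noise(n_eeg, fs, 8, 15) +
            0.08 * band_limited_noise(n_eeg, fs, 15, 30)
    ch <- delta + rest
    eeg[, c_] <- 40 * ch / sd(ch)            # ~40 uV rms
  }

  truth <- list(envelope = env_sec, map = map,
                flat_sec = integer(0), burst_sec = integer(0),
                bp_drop_sec = integer(0))
  interventions <- numeric(0)
  if (artifacts) {
    n_events <- max(1L, as.integer(duration_h * 2))
    for (i in seq_len(n_events)) {
      # flat-line: all channels silent for 5-10 s
      t0 <- sample.int(n_sec - 12L, 1L)
      len <- sample(5:10, 1L)
      eeg[(t0 * fs + 1L):((t0 + len) * fs), ] <- 0
      truth$flat_sec <- union(truth$flat_sec, t0:(t0 + len - 1L))
      # high-amplitude burst on all channels for 3-6 s
      t1 <- sample.int(n_sec - 8L, 1L)
      len1 <- sample(3:6, 1L)
      idx <- (t1 * fs + 1L):((t1 + len1) * fs)
      eeg[idx, ] <- eeg[idx, ] + 1000 * sin(2 * pi * 2 * seq_along(idx) / fs)
      truth$burst_sec <- union(truth$burst_sec, t1:(t1 + len1 - 1L))
      # BP dropout: transducer disconnected for 3-5 s
      t2 <- sample.int(n_sec - 6L, 1L)
      len2 <- sample(3:5, 1L)
      sp[(t2 + 1L):(t2 + len2)] <- 4
      dp[(t2 + 1L):(t2 + len2)] <- 2
      truth$bp_drop_sec <- union(truth$bp_drop_sec, t2:(t2 + len2 - 1L))
    }
    if (duration_h >= 1)
      interventions <- sort(sample.int(n_sec, max(1L, as.integer(duration_h))))
  }
  truth$flat_sec <- sort(truth$flat_sec)
  truth$burst_sec <- sort(setdiff(truth$burst_sec, truth$flat_sec))

  list(eeg = eeg_record(eeg, fs = fs),
       bp = data.frame(time_s = 0:(n_sec - 1L), sp_mmHg = sp, dp_mmHg = dp),
       interventions = interventions, truth = truth)
}

#' Preprocess a synthetic (or real) recording into an aligned pair
#'
#' Convenience wrapper chaining [filter_and_downsample()],
#' [mark_eeg_artifacts()], [extract_band_power()], [compute_map()],
#' [clean_bp()] and [synchronize()] with package defaults.
#'
#' @param rec list with `eeg`, `bp`, `interventions` as produced by
#'   [gen_synthetic_recording()].
#' @return an [aligned_pair()].
#' @export
preprocess_recording <- function(rec) {
  eeg64 <- filter_and_downsample(rec$eeg)
  valid <- mark_eeg_artifacts(rec$eeg)
  feats <- extract_band_power(eeg64, valid_sec = valid)
  bp <- compute_map(rec$bp$time_s, rec$bp$sp_mmHg, rec$bp$dp_mmHg)
  bp <- clean_bp(bp, rec$interventions)
  synchronize(feats, bp)
}
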