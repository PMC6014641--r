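#' Specification of a synthetic cohort
#'
#' Describes a cohort in which each subject's EEG-MAP coupling strength is
#' tied to a CRIB-like illness score with a controllable Spearman rank
#' correlation: (score, coupling) are drawn from a Gaussian copula whose
#' Pearson parameter `2 sin(pi rho / 6)` yields the requested Spearman
#' `rho`, then mapped to the integer score range and the coupling range.
#'
#' @param n_subjects number of subjects (a warning is issued below 5:
#'   association tests are underpowered).
#' @param coupling_range `(low, high)` coupling strengths in \[0, 1\].
#' @param score_range `(low, high)` integer score range (CRIB-like, 1-27).
#' @param score_coupling_rho target Spearman correlation between score and
#'   coupling, in \[-1, 1\].
#' @param recording_hours per-subject feature-series duration.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25L, coupling_range = c(0.1, 0.9),
                        score_range = c(1L, 17L), score_coupling_rho = -0.6,
                        recording_hours = 1.5, seed = 1L) {
  if (n_subjects < 5L) warning("n_subjects < 5: association underpowered")
  if (coupling_range[1] >= coupling_range[2] ||
      score_range[1] >= score_range[2])
    stop("ranges must have low < high", call. = FALSE)
  if (any(coupling_range < 0 | coupling_range > 1))
    stop("coupling_range must be within [0, 1]", call. = FALSE)
  if (abs(score_coupling_rho) > 1)
    stop("score_coupling_rho must be in [-1, 1]", call. = FALSE)
  if (recording_hours <= 0) stop("recording_hours must be > 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 coupling_range = as.numeric(coupling_range),
                 score_range = as.integer(score_range),
                 score_coupling_rho = score_coupling_rho,
                 recording_hours = recording_hours,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Feature-level subject: slow MAP series plus four band-power series at
# 1 Hz, with band-1 log-power correlated with MAP at strength `coupling`.
gen_subject_features <- function(n_sec, coupling) {
  z_m <- slow_process(n_sec)
  map <- 35 + 4 * z_m
  bp <- matrix(NA_real_, n_sec, 4L)
  z1 <- coupling * z_m + sqrt(max(0, 1 - coupling^2)) * slow_process(n_sec)
  bp[, 1] <- 8 * exp(0.5 * z1)                 # delta power, uV^2
  for (b in 2:4)
    bp[, b] <- (6 - b) * exp(0.4 * slow_process(n_sec))
  aligned_pair(0:(n_sec - 1L), map, bp, rep(TRUE, n_sec))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject (score, coupling) pairs with the planted rank
#' correlation of the spec and produces per-subject data plus a clinical
#' table with the columns of a neonatal cohort description (`subject`,
#' `ga_weeks`, `bw_g`, `crib`, `apgar5`, `sex`, `cord_ph`, `duration_h`).
#' At `signal_level = "features"` (default) each subject is an
#' [aligned_pair()] of 1 Hz smoothed MAP and band powers, ready for the
#' windowed coupling measures; at `"raw"` each subject is a full
#' [gen_synthetic_recording()] output that must be run through
#' [preprocess_recording()].
#'
#' @param spec a [cohort_spec()].
#' @param signal_level `"features"` or `"raw"`.
#' @return list: `clinical` (data.frame, one row per subject, including
#'   the latent `coupling`), `subjects` (list).
#' @export
gen_synthetic_cohort <- function(spec, signal_level = c("features", "raw")) {
  stopifnot(inherits(spec, "cohort_spec"))
  signal_level <- match.arg(signal_level)
  set.seed(spec$seed)
  n <- spec$n_subjects
  rho_p <- 2 * sin(pi * spec$score_coupling_rho / 6)
  z1 <- rnorm(n)
  # impose the target correlation in-sample (not just in expectation):
  # orthogonalize the jitter against z1 so small cohorts still carry the
  # nominal association
  z1s <- (z1 - mean(z1)) / sd(z1)
  e <- rnorm(n)
  e <- e - mean(e) - z1s * sum(z1s * (e - mean(e))) / sum(z1s^2)
  e <- e / sd(e)
  z2 <- rho_p * z1s + sqrt(1 - rho_p^2) * e
  sr <- spec$score_range
  score <- pmin(pmax(as.integer(round(
    sr[1] + (sr[2] - sr[1]) * pnorm(z1))), sr[1]), sr[2])
  cr <- spec$coupling_range
  coupling <- cr[1] + (cr[2] - cr[1]) * pnorm(z2)
  ga <- round(23 + 8 * pnorm(-z1) + runif(n, -1, 1))
  clinical <- data.frame(
    subject = seq_len(n),
    ga_weeks = pmin(pmax(ga, 23), 31),
    bw_g = as.integer(round(500 + 120 * (pmin(pmax(ga, 23), 31) - 23) +
                              rnorm(n, 0, 120))),
    crib = score,
    apgar5 = pmin(pmax(as.integer(round(8 - 0.2 * score + rnorm(n, 0, 1))),
                       1L), 10L),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cord_ph = round(7.2 + rnorm(n, 0, 0.12), 2),
    duration_h = spec$recording_hours,
    coupling = coupling)
  n_sec <- as.integer(round(spec$recording_hours * 3600))
  subject_seeds <- sample.int(.Machine$integer.max, n)
  subjects <- lapply(seq_len(n), function(i) {
    set.seed(subject_seeds[i])
    if (signal_level == "features") gen_subject_features(n_sec, coupling[i])
    else gen_synthetic_recording(spec$recording_hours, coupling[i],
                                 direction = "map_to_eeg",
                                 seed = subject_seeds[i])
  })
  list(clinical = clinical, subjects = subjects)
}

#' The shipped clinical reference table
#'
#' Reads the 25-subject neonatal clinical table distributed with the
#' package (`extdata/clinical_table1.csv`): gestational age, birth weight,
#' CRIB II score, 5-minute Apgar, sex, cord pH and recording duration per
#' subject.
#'
#' @return data.frame with one row per subject.
#' @export
clinical_table1 <- function() {
  read.csv(system.file("extdata", "clinical_table1.csv", package = "eegbp",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Run the windowed AMI pipeline over a feature-level cohort
#'
#' For each subject computes the windowed AMI series for a band and
#' summarizes it as the per-subject median, returning the summary table
#' used by the association stage.
#'
#' @param cohort a [gen_synthetic_cohort()] result at feature level.
#' @param band band index (default 1, the delta band).
#' @param win a [window_spec()].
#' @return data.frame of [summarize_subject()] rows.
#' @export
cohort_ami_summaries <- function(cohort, band = 1L, win = window_spec()) {
  rows <- lapply(seq_len(nrow(cohort$clinical)), function(i) {
    pair <- cohort$subjects[[i]]
    cs <- windowed_ami(pair, band, win)
    summarize_subject(cs, cohort$clinical[i, , drop = FALSE],
                      map_median = median(pair$map_smoothed[pair$valid]))
  })
  do.call(rbind, rows)
}
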