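#' Summarize a subject's coupling series
#'
#' Medians of each coupling measure per band over the subject's valid
#' windows (optionally restricted to the first hours of life), plus the
#' median smoothed MAP, attached to the subject's clinical row.
#'
#' @param coupling data.frame binding coupling series rows
#'   (`window_start_s`, `value`, `measure`, `band`).
#' @param clinical_row one-row data.frame with at least `subject` and
#'   `crib`.
#' @param map_median median smoothed MAP (mmHg) over valid seconds, or NA.
#' @param first_h if non-NULL, keep only windows starting before
#'   `first_h * 3600` seconds (e.g. 24 for the first day of life).
#' @return one-row data.frame: clinical columns plus
#'   `<measure>_b<band>` median coupling columns and `map_median`; NULL if
#'   the subject has no evaluable window.
#' @export
summarize_subject <- function(coupling, clinical_row, map_median = NA_real_,
                              first_h = NULL) {
  if (!is.null(first_h))
    coupling <- coupling[coupling$window_start_s < first_h * 3600, ,
                         drop = FALSE]
  if (nrow(coupling) == 0L) return(NULL)
  out <- clinical_row
  for (m in unique(coupling$measure))
    for (b in unique(coupling$band[coupling$measure == m])) {
      v <- coupling$value[coupling$measure == m & coupling$band == b]
      out[[paste0(m, "_b", b)]] <- median(v)
    }
  out$map_median <- map_median
  out$n_windows <- nrow(coupling)
  out
}

#' Spearman rank association between subject coupling and illness score
#'
#' Spearman's rho with average ranks for ties and a two-tailed p-value
#' (t approximation), plus the least-squares regression line of value on
#' score.
#'
#' @param values per-subject coupling medians.
#' @param scores per-subject illness scores (e.g. CRIB II), paired.
#' @return list of class `association`: `r`, `p`, `n`, `slope`,
#'   `intercept`.
#' @export
spearman_association <- function(values, scores) {
  ok <- stats::complete.cases(values, scores)
  values <- values[ok]; scores <- scores[ok]
  n <- length(values)
  if (n < 5L) stop("need at least 5 paired subjects", call. = FALSE)
  if (sd(scores) == 0) stop("constant scores", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(values, scores, method = "spearman", exact = FALSE))
  fit <- lm(values ~ scores)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "association")
}

#' Bootstrap percentile confidence interval for Spearman's rho
#'
#' Resamples subject pairs with replacement, recomputes rho, and returns
#' the percentile 95% interval; the association is flagged significant
#' when the interval excludes zero.
#'
#' @inheritParams spearman_association
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list: `low`, `high`, `excludes_zero`.
#' @export
bootstrap_ci <- function(values, scores, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  n <- length(values)
  if (n < 5L) stop("need at least 5 paired subjects", call. = FALSE)
  set.seed(seed)
  rs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    if (sd(scores[idx]) == 0 || sd(values[idx]) == 0) return(NA_real_)
    cor(values[idx], scores[idx], method = "spearman")
  }, numeric(1))
  qs <- quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(low = unname(qs[1]), high = unname(qs[2]),
       excludes_zero = unname(qs[1] > 0 || qs[2] < 0))
}

#' Holm-Bonferroni step-down multiple-comparison correction
#'
#' Sorted p-values `p_(i)` are compared against `alpha / (n - i + 1)`;
#' testing stops at the first failure and all later hypotheses are
#' retained.  For a family of 5 at alpha 0.05 the smallest p must
#' therefore be below 0.01.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise level (default 0.05).
#' @return data.frame in the input order: `p`, `threshold`, `significant`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  n <- length(p_values)
  ord <- order(p_values)
  thresh <- alpha / (n - seq_len(n) + 1)
  sig_sorted <- logical(n)
  for (i in seq_len(n)) {
    if (p_values[ord[i]] <= thresh[i]) sig_sorted[i] <- TRUE else break
  }
  out <- data.frame(p = p_values, threshold = NA_real_, significant = NA)
  out$threshold[ord] <- thresh
  out$significant[ord] <- sig_sorted
  out
}

#' Test of two dependent overlapping correlations (Steiger's z)
#'
#' Tests equality of `r_ab` and `r_ac` measured on the same sample and
#' sharing variable `a`, using Steiger's modification of Dunn and Clark's
#' z with a backtransformed average correlation:
#' `z = (z_ab - z_ac) sqrt((n - 3) / (2 (1 - s)))`, where `z_.` are Fisher
#' transforms and `s` is the covariance term determined by `r_bc` and the
#' mean of the two correlations.
#'
#' @param r_ab,r_ac the two correlations sharing variable `a`, in (-1, 1).
#' @param r_bc correlation between the non-shared variables, in (-1, 1).
#' @param n sample size, > 3.
#' @return list: `z`, `p` (two-tailed).
#' @export
dependent_correlation_test <- function(r_ab, r_ac, r_bc, n) {
  if (any(abs(c(r_ab, r_ac, r_bc)) >= 1))
    stop("correlations must be in (-1, 1)", call. = FALSE)
  if (n <= 3) stop("n must be > 3", call. = FALSE)
  rm_ <- (r_ab + r_ac) / 2
  # covariance of the two dependent correlations (Steiger 1980, Eq 3 & 10)
  cov_num <- r_bc * (1 - 2 * rm_^2) - 0.5 * rm_^2 *
    (1 - 2 * rm_^2 - r_bc^2)
  s <- cov_num / (1 - rm_^2)^2
  z1 <- atanh(r_ab); z2 <- atanh(r_ac)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Association grid across measures and bands
#'
#' Runs [spearman_association()] and [bootstrap_ci()] for every
#' `<measure>_b<band>` column of a subject summary table against the CRIB
#' score, mirroring the measure-by-band layout of a cohort report.
#'
#' @param summaries data.frame of [summarize_subject()] rows.
#' @param score_col name of the score column (default `"crib"`).
#' @param n_boot,seed bootstrap parameters.
#' @return data.frame: `measure`, `band`, `r`, `p`, `ci_low`, `ci_high`,
#'   `ci_excludes_zero`, `n`.
#' @export
association_grid <- function(summaries, score_col = "crib",
                             n_boot = 1000L, seed = 1L) {
  cols <- grep("_b[1-4]$", names(summaries), value = TRUE)
  rows <- lapply(cols, function(cl) {
    a <- spearman_association(summaries[[cl]], summaries[[score_col]])
    ci <- bootstrap_ci(summaries[[cl]], summaries[[score_col]],
                       n_boot = n_boot, seed = seed)
    data.frame(measure = sub("_b[1-4]$", "", cl),
               band = as.integer(sub(".*_b", "", cl)),
               r = a$r, p = a$p, ci_low = ci$low, ci_high = ci$high,
               ci_excludes_zero = ci$excludes_zero, n = a$n)
  })
  do.call(rbind, rows)
}
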