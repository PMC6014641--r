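#' Quantize a MAP window with the integer-range rule
#'
#' The number of labels equals the span of integer mmHg values covered by
#' the window, `floor(max) - floor(min) + 1`, with uniform 1-mmHg bins
#' anchored at integer boundaries (label = `floor(v) - floor(min)`).  This
#' rule deliberately assigns a single label to a window in which MAP
#' fluctuates within 1 mmHg, preventing the artificial creation of dynamics
#' from measurement-scale jitter.
#'
#' @param v numeric vector of valid MAP values (mmHg), non-empty.
#' @return object of class `label_seq`: integer labels in `0 .. n_labels - 1`
#'   with attribute `n_labels`.
#' @export
quantize_map <- function(v) {
  if (length(v) == 0L || anyNA(v)) stop("window must be non-empty and complete",
                                        call. = FALSE)
  lo <- floor(min(v))
  labels <- as.integer(floor(v) - lo)
  new_label_seq(labels, as.integer(floor(max(v)) - lo + 1))
}

#' Quantize an EEG band-power window into equal-width bins
#'
#' Equal-width bins spanning the `[min, max]` range of the window; the
#' default of 35 bins is the granularity that maximizes mean adjusted
#' mutual information across subjects in the clinical calibration (see
#' [select_n_bins()]).
#'
#' @param v numeric vector of valid power values, non-empty.
#' @param n_bins number of bins (labels), >= 1.
#' @return a `label_seq`.
#' @export
quantize_power <- function(v, n_bins = 35L) {
  if (length(v) == 0L || anyNA(v)) stop("window must be non-empty and complete",
                                        call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2] || n_bins == 1L)
    return(new_label_seq(integer(length(v)), 1L))
  w <- (rng[2] - rng[1]) / n_bins
  labels <- pmin(as.integer(floor((v - rng[1]) / w)), n_bins - 1L)
  new_label_seq(labels, n_bins)
}

new_label_seq <- function(labels, n_labels) {
  structure(as.integer(labels), n_labels = as.integer(n_labels),
            class = "label_seq")
}

n_labels <- function(x) {
  if (inherits(x, "label_seq")) attr(x, "n_labels") else max(x) + 1L
}

as_label_seq <- function(x) {
  if (inherits(x, "label_seq")) return(x)
  x <- as.integer(x)
  if (min(x) < 0) stop("labels must be >= 0", call. = FALSE)
  new_label_seq(x, max(x) + 1L)
}

#' Contingency table of two label sequences
#'
#' @param x,y label sequences of equal length.
#' @return list with counts matrix `n_xy`, row margins `a_x`, column
#'   margins `b_y`, and total `N`.  Empty rows/columns are kept.
#' @export
contingency <- function(x, y) {
  x <- as_label_seq(x); y <- as_label_seq(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n_xy <- table(factor(x, levels = 0:(n_labels(x) - 1L)),
                factor(y, levels = 0:(n_labels(y) - 1L)))
  n_xy <- matrix(as.integer(n_xy), nrow = n_labels(x))
  list(n_xy = n_xy, a_x = rowSums(n_xy), b_y = colSums(n_xy),
       N = length(x))
}

#' Plug-in mutual information of two label sequences (bits)
#'
#' `MI(X, Y) = sum p(x, y) log2(p(x, y) / (p(x) p(y)))` with empirical
#' probabilities from the contingency table.
#'
#' @param x,y label sequences of equal length.
#' @return MI in bits, >= 0.
#' @export
mutual_information <- function(x, y) {
  ct <- contingency(x, y)
  p <- ct$n_xy / ct$N
  px <- ct$a_x / ct$N; py <- ct$b_y / ct$N
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

entropy_bits <- function(x) {
  p <- tabulate(as.integer(x) + 1L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Exact expected mutual information under random permutation (bits)
#'
#' The expectation of the plug-in MI over all assignments of labels with the
#' given margins, i.e. under the hypergeometric model of a random
#' permutation of one sequence against the other.  For each cell `(x, y)`
#' the cell count `n_xy` ranges over `max(1, a_x + b_y - N) ..
#' min(a_x, b_y)` and each term is weighted by its hypergeometric
#' probability; factorials are evaluated through `lgamma` so windows of
#' hundreds to thousands of samples do not overflow.
#'
#' @param a_x,b_y margin counts (non-negative integers); zero margins are
#'   skipped (they contribute nothing).
#' @param N total count; must equal `sum(a_x)` and `sum(b_y)`.
#' @return expected MI in bits.
#' @export
expected_mi <- function(a_x, b_y, N) {
  if (sum(a_x) != N || sum(b_y) != N)
    stop("margins inconsistent with N", call. = FALSE)
  a_x <- a_x[a_x > 0]; b_y <- b_y[b_y > 0]
  tot <- 0
  lgN <- lgamma(N + 1)
  for (ai in a_x) {
    la <- lgamma(ai + 1) + lgamma(N - ai + 1)
    for (bj in b_y) {
      lo <- max(1, ai + bj - N); hi <- min(ai, bj)
      nij <- lo:hi
      lw <- la + lgamma(bj + 1) + lgamma(N - bj + 1) - lgN -
        lgamma(nij + 1) - lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      tot <- tot + sum(nij / N * log2(N * nij / (ai * bj)) * exp(lw))
    }
  }
  tot
}

#' Adjusted mutual information of two label sequences
#'
#' `AMI = (MI - E[MI]) / (max(H(X), H(Y)) - E[MI])`, where `E[MI]` is the
#' exact permutation expectation of [expected_mi()].  AMI equals 1 for
#' identical sequences and is close to 0 (possibly slightly negative) for
#' independent ones, at any label granularity; unlike raw MI it does not
#' inflate as the number of labels grows.
#'
#' @param x,y label sequences of equal length; at least one must be
#'   non-constant.
#' @return AMI (unitless, <= 1).
#' @export
adjusted_mi <- function(x, y) {
  x <- as_label_seq(x); y <- as_label_seq(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  hx <- entropy_bits(x); hy <- entropy_bits(y)
  if (hx == 0 && hy == 0)
    stop("AMI undefined: both sequences constant", call. = FALSE)
  ct <- contingency(x, y)
  emi <- expected_mi(ct$a_x, ct$b_y, ct$N)
  (mutual_information(x, y) - emi) / (max(hx, hy) - emi)
}

#' Select the EEG power bin count maximizing corpus-mean AMI
#'
#' For each candidate bin count, quantizes every aligned window (MAP by the
#' integer-range rule, power into the candidate number of bins), averages
#' AMI over windows within subject and then over subjects, and returns the
#' candidate with the largest grand mean.
#'
#' @param corpus list of subjects, each a list of windows, each window a
#'   list with numeric vectors `map` and `power`.
#' @param candidate_bins integer vector of candidate bin counts.
#' @return the selected bin count (integer).
#' @export
select_n_bins <- function(corpus, candidate_bins) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (length(candidate_bins) == 1L) return(as.integer(candidate_bins))
  grand <- vapply(candidate_bins, function(nb) {
    per_subj <- vapply(corpus, function(subj) {
      vals <- vapply(subj, function(w) {
        lx <- quantize_map(w$map)
        ly <- quantize_power(w$power, nb)
        if (entropy_bits(lx) == 0 && entropy_bits(ly) == 0) return(NA_real_)
        adjusted_mi(lx, ly)
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    mean(per_subj, na.rm = TRUE)
  }, numeric(1))
  as.integer(candidate_bins[which.max(grand)])
}

#' Windowed adjusted mutual information between MAP and a band power
#'
#' Applies the moving-window scheme of [windowed_correlation()]; within
#' each evaluable window the smoothed MAP is quantized with the
#' integer-range rule and the band power into `n_bins` equal-width bins,
#' and their AMI is computed.  Windows in which both quantized sequences
#' are constant are skipped.
#'
#' @param pair an [aligned_pair()].
#' @param band band index 1-4.
#' @param win a [window_spec()].
#' @param n_bins EEG power bin count (default 35).
#' @return a coupling series data.frame (`window_start_s`, `value`,
#'   `measure`, `band`).
#' @export
windowed_ami <- function(pair, band, win = window_spec(), n_bins = 35L) {
  eval_windows(pair, band, win, measure = "ami", function(m, p) {
    lx <- quantize_map(m)
    ly <- quantize_power(p, n_bins)
    if (entropy_bits(lx) == 0 && entropy_bits(ly) == 0) return(NA_real_)
    adjusted_mi(lx, ly)
  })
}
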