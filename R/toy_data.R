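#' Specification of a sinusoid-plus-noise toy signal
#'
#' Describes a noiseless reference signal built as a sum of sinusoids on the
#' unit interval, and the standard deviation of additive Gaussian noise used
#' to produce its observed counterpart.  The default amplitudes and
#' frequencies reproduce the worked toy example used throughout the package's
#' validation studies: `y0 = 2.8 sin(2*pi*1000 x) + 1.2 sin(2*pi*3000 x) +
#' 0.2 sin(2*pi*500 x)`, whose correlation with `y0 + N(0, 1)` is about 0.91.
#'
#' @param amplitudes numeric vector of sinusoid amplitudes (unitless).
#' @param frequencies numeric vector of frequencies in cycles per unit `x`;
#'   must have the same length as `amplitudes`.
#' @param noise_sd standard deviation of the additive Gaussian noise, >= 0.
#' @param n_samples number of equally spaced samples of `x` in `[0, 1)`.
#'   The default 1800 matches one 30-minute analysis window at 1 Hz.
#' @param seed integer seed making draws reproducible.
#' @return An object of class `toy_spec`.
#' @export
toy_spec <- function(amplitudes = c(2.8, 1.2, 0.2),
                     frequencies = c(1000, 3000, 500),
                     noise_sd = 1, n_samples = 1800, seed = 1L) {
  if (length(amplitudes) == 0L)
    stop("amplitudes must be non-empty", call. = FALSE)
  if (length(amplitudes) != length(frequencies))
    stop("amplitudes and frequencies must have equal length", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  structure(list(amplitudes = as.numeric(amplitudes),
                 frequencies = as.numeric(frequencies),
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate the toy sinusoid pair (reference, noisy)
#'
#' Samples `y0`, the sum of sinusoids described by `spec`, on `n_samples`
#' equally spaced points of `[0, 1)` (an integer number of full periods of
#' every component, so sample moments match the closed-form sinusoid
#' variance `sum(a^2)/2`), and returns it together with `y = y0 + N(0,
#' noise_sd^2)`.
#'
#' @param spec a [toy_spec()].
#' @return list with `x`, `y0`, `y`.
#' @export
gen_toy_sinusoid <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_samples
  x <- (seq_len(n) - 1) / n
  y0 <- rep(0, n)
  for (k in seq_along(spec$amplitudes))
    y0 <- y0 + spec$amplitudes[k] * sin(2 * pi * spec$frequencies[k] * x)
  set.seed(spec$seed)
  y <- y0 + rnorm(n, sd = spec$noise_sd)
  list(x = x, y0 = y0, y = y)
}

#' Sweep additive noise levels on the toy pair
#'
#' For each noise standard deviation, draws a fresh noisy copy of the
#' reference signal.  Used to map how correlation and adjusted mutual
#' information degrade with additive noise; the closed-form expectation for
#' the correlation at noise level `s` is `sqrt(V / (V + s^2))` with
#' `V = sum(amplitudes^2) / 2`.
#'
#' @param spec a [toy_spec()]; its `noise_sd` field is ignored.
#' @param noise_levels non-empty numeric vector of noise sds, all >= 0.
#' @return list with `y0` and a list `pairs`, one `(noise_sd, y)` per level.
#' @export
gen_noise_sweep <- function(spec, noise_levels) {
  stopifnot(inherits(spec, "toy_spec"))
  if (length(noise_levels) == 0L)
    stop("noise_levels must be non-empty", call. = FALSE)
  if (any(noise_levels < 0))
    stop("noise levels must be >= 0", call. = FALSE)
  base <- gen_toy_sinusoid(spec)
  set.seed(spec$seed)
  pairs <- lapply(noise_levels, function(s)
    list(noise_sd = s, y = base$y0 + rnorm(spec$n_samples, sd = s)))
  list(x = base$x, y0 = base$y0, pairs = pairs)
}

#' Adjusted mutual information of a toy signal pair
#'
#' Quantizes both continuous sequences with the integer-range rule (number
#' of labels equal to the span of integer values in the sequence, the same
#' rule applied to MAP in the clinical pipeline) and computes their adjusted
#' mutual information.  The integer-range rule is the package's
#' signal-agnostic quantization default; the 35-bin rule used for EEG band
#' power is a calibration specific to that feature and is not applied to
#' toy signals.
#'
#' @param a,b numeric sequences of equal length.
#' @return AMI (unitless).
#' @export
toy_ami <- function(a, b) {
  adjusted_mi(quantize_map(a), quantize_map(b))
}
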