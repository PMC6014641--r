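#' Specification of a coupled Gaussian autoregressive pair
#'
#' Describes a driver/response pair used as a directional oracle for
#' transfer entropy: the source `x` is IID Gaussian with sd `noise_sd`, and
#' (for `direction = "x_to_y"`) the target follows
#' `y_t = a y_{t-1} + c x_{t-lag} + e_t`, `e_t ~ N(0, noise_sd^2)`.  With
#' embedding `d = u = 1` and `lag = 1` the true transfer entropy from `x`
#' to `y` is `0.5 * log(1 + c^2 Var(x) / noise_sd^2)` nats and zero in the
#' reverse direction conditional on `y`'s own past being insufficient
#' (for IID x the reverse TE is exactly 0).
#'
#' @param n_samples number of retained samples (after burn-in).
#' @param self_coeff AR(1) coefficient `a`, `|a| < 1`.
#' @param coupling_coeff coupling strength `c`.
#' @param lag coupling delay in samples, >= 1.
#' @param direction one of `"x_to_y"`, `"y_to_x"`, `"none"`.
#' @param noise_sd innovation standard deviation, > 0.
#' @param seed integer seed.
#' @return object of class `coupled_ar_spec`.
#' @export
coupled_ar_spec <- function(n_samples = 5000, self_coeff = 0.5,
                            coupling_coeff = 0.5, lag = 1L,
                            direction = c("x_to_y", "y_to_x", "none"),
                            noise_sd = 1, seed = 1L) {
  direction <- match.arg(direction)
  if (abs(self_coeff) >= 1)
    stop("|self_coeff| must be < 1 for stationarity", call. = FALSE)
  if (lag < 1) stop("lag must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), self_coeff = self_coeff,
                 coupling_coeff = coupling_coeff, lag = as.integer(lag),
                 direction = direction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coupled_ar_spec")
}

#' Generate a coupled AR pair
#'
#' @param spec a [coupled_ar_spec()].
#' @return list with numeric vectors `x` and `y` of length `n_samples`.
#'   For `direction = "y_to_x"` the roles are swapped (y drives x); for
#'   `"none"` the two are independent AR(1) processes.
#' @export
gen_coupled_ar <- function(spec) {
  stopifnot(inherits(spec, "coupled_ar_spec"))
  n <- spec$n_samples; burn <- 200L
  m <- n + burn + spec$lag
  set.seed(spec$seed)
  drive <- rnorm(m, sd = spec$noise_sd)      # IID source
  eps <- rnorm(m, sd = spec$noise_sd)        # target innovations
  a <- spec$self_coeff
  c_ <- if (spec$direction == "none") 0 else spec$coupling_coeff
  resp <- numeric(m)
  for (t in seq(spec$lag + 1L, m))
    resp[t] <- a * resp[t - 1L] + c_ * drive[t - spec$lag] + eps[t]
  keep <- seq(m - n + 1L, m)
  if (spec$direction == "y_to_x") {
    list(x = resp[keep], y = drive[keep])
  } else if (spec$direction == "none") {
    # independent AR(1) pair with the same marginal dynamics
    x2 <- numeric(m)
    innov <- rnorm(m, sd = spec$noise_sd)
    for (t in 2:m) x2[t] <- a * x2[t - 1L] + innov[t]
    list(x = x2[keep], y = resp[keep])
  } else {
    list(x = drive[keep], y = resp[keep])
  }
}
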