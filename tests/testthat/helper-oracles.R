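# Independent brute-force oracles used across test files.  These are
# deliberately written as direct transcriptions of definitions, not calls
# into the package's own code paths.

# Plug-in MI (bits) by explicit term-by-term summation over observed pairs.
oracle_mi <- function(x, y) {
  n <- length(x)
  tot <- 0
  for (ux in unique(x)) for (uy in unique(y)) {
    pxy <- sum(x == ux & y == uy) / n
    if (pxy == 0) next
    tot <- tot + pxy * log2(pxy / ((sum(x == ux) / n) * (sum(y == uy) / n)))
  }
  tot
}

# Mean MI over all N! permutations of y against x (N <= 8).
oracle_perm_mean_mi <- function(x, y) {
  n <- length(y)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  mean(vapply(perms(seq_len(n)), function(p) oracle_mi(x, y[p]), numeric(1)))
}

# Brute-force KSG transfer entropy in plain R (max-norm, strict counts).
oracle_ksg_te <- function(yf, yp, xp, K) {
  n <- length(yf)
  acc <- 0
  for (i in seq_len(n)) {
    d_yp <- apply(abs(yp - rep(yp[i, ], each = n)), 1, max)
    d_f <- abs(yf - yf[i])
    d_xp <- apply(abs(xp - rep(xp[i, ], each = n)), 1, max)
    d_ypf <- pmax(d_yp, d_f)
    d_ypx <- pmax(d_yp, d_xp)
    dj <- pmax(d_ypf, d_xp)
    dj[i] <- Inf
    eps <- sort(dj)[K]
    acc <- acc + digamma(sum(d_yp[-i] < eps) + 1) -
      digamma(sum(d_ypf[-i] < eps) + 1) - digamma(sum(d_ypx[-i] < eps) + 1)
  }
  digamma(K) + acc / n
}

# Sinusoid-sum theoretical correlation at additive noise sd s.
oracle_sin_corr <- function(amplitudes, s) {
  v <- sum(amplitudes^2) / 2
  sqrt(v / (v + s^2))
}

make_pair <- function(n, map, power, valid = rep(TRUE, n)) {
  bp <- matrix(rnorm(4 * n), n, 4)
  bp[, 1] <- power
  aligned_pair(0:(n - 1), map, bp, valid)
}
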