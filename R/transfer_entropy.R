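#' Embedding specification for transfer entropy
#'
#' @param d_x,d_y source / target embedding dimensions (samples of past).
#' @param u prediction time in samples (default 1).
#' @param K nearest neighbours for the KSG estimator (default 4, the
#'   recommended bias/variance compromise).
#' @return object of class `embedding_spec`.
#' @export
embedding_spec <- function(d_x = 1L, d_y = 1L, u = 1L, K = 4L) {
  if (d_x < 1 || d_y < 1 || u < 1 || K < 1)
    stop("d_x, d_y, u, K must all be >= 1", call. = FALSE)
  structure(list(d_x = as.integer(d_x), d_y = as.integer(d_y),
                 u = as.integer(u), K = as.integer(K)),
            class = "embedding_spec")
}

# Rank-normalize to (0, 1) with a deterministic tiny jitter that breaks the
# exact distance ties the integer rank grid would otherwise create in the
# max-norm neighbour counts.  TE/MI are invariant to monotone marginal
# transforms in the continuous limit, and rank scaling stabilizes the
# neighbour searches across signals of very different units.
rank_normalize <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "first") / (n + 1)
  r + runif(n, -1e-8, 1e-8)
}

# Delay-embed: rows are (x_{t-d+1}, ..., x_t) for t = d .. n.
delay_embed <- function(x, d) {
  n <- length(x)
  out <- vapply(seq_len(d), function(k) x[(d - k + 1L):(n - k + 1L)],
                numeric(n - d + 1L))
  matrix(out, ncol = d)
}

#' Active information storage (nats)
#'
#' KSG-estimated mutual information between the `d`-sample past vector of a
#' process and its next value, `A_X(d) = MI(X_t^d, X_{t+1})` — the amount
#' of the process's own history usable to predict its future.  Used to
#' choose the embedding dimension for transfer entropy.
#'
#' @param x numeric sequence.
#' @param d embedding dimension (past length).
#' @param K nearest neighbours (default 4).
#' @return AIS in nats (may be slightly negative from estimator bias).
#' @export
active_information_storage <- function(x, d, K = 4L) {
  n <- length(x)
  if (n <= d + K + 1L) stop("sequence too short for d and K", call. = FALSE)
  z <- rank_normalize(x)
  past <- delay_embed(z, d)             # rows end at t = d..n
  past <- past[seq_len(nrow(past) - 1L), , drop = FALSE]
  fut <- matrix(z[(d + 1L):n], ncol = 1L)
  ksg_mi_cpp(past, fut, as.integer(K))
}

#' Select an embedding dimension by active information storage
#'
#' Forward selection on bias-corrected AIS.  At each candidate dimension
#' the AIS is corrected by the mean AIS of shuffled copies of the sequence
#' (same dimension, history destroyed): the KSG estimator's bias grows
#' with the embedding dimension, and the shuffled baseline tracks exactly
#' that growth.  The dimension is extended from `d` to `d + 1` only while
#' the corrected AIS gain exceeds a noise floor (twice the dispersion of
#' the shuffled estimates, at least 0.06 nats); selection stops at the
#' first non-significant gain.  The parsimony rule keeps flat AIS
#' plateaus at the shorter embedding.
#'
#' @param x numeric sequence.
#' @param d_max maximum embedding dimension considered (default 5).
#' @param K nearest neighbours (default 4).
#' @param n_shuffle shuffled baselines per dimension (default 2).
#' @return selected dimension (integer) with attribute `ais`, the
#'   bias-corrected AIS profile in nats up to the last dimension tried.
#' @export
select_embedding <- function(x, d_max = 5L, K = 4L, n_shuffle = 2L) {
  if (d_max < 1) stop("d_max must be >= 1", call. = FALSE)
  d_sel <- 1L
  profile <- numeric(0)
  prev <- NA_real_
  for (d in seq_len(d_max)) {
    a <- active_information_storage(x, d, K)
    nul <- vapply(seq_len(n_shuffle), function(i)
      active_information_storage(sample(x), d, K), numeric(1))
    corrected <- a - mean(nul)
    profile <- c(profile, corrected)
    if (d == 1L) { prev <- corrected; next }
    gain_floor <- max(2 * sd(nul), 0.06)
    if (corrected - prev >= gain_floor) {
      d_sel <- d
      prev <- corrected
    } else break
  }
  structure(d_sel, ais = profile)
}

#' KSG transfer entropy (nats)
#'
#' Transfer entropy from `x` to `y`: the reduction in uncertainty of
#' `y_{t+u}` given the source past `x_t^{d_x}` beyond what the target's own
#' past `y_t^{d_y}` provides.  Estimated with the
#' Kraskov-Stogbauer-Grassberger nearest-neighbour method: `K` neighbours
#' in the joint space `(y_{t+u}, y_t^{d_y}, x_t^{d_x})` under the max-norm,
#' with the K-th neighbour distance projected onto the marginal spaces for
#' strict-inequality counts averaged through digamma functions.  Both
#' streams are rank-normalized before embedding.  Small negative estimates
#' can occur and are reported as-is.
#'
#' @param x source sequence.
#' @param y target sequence (same length).
#' @param emb an [embedding_spec()].
#' @return TE in nats.
#' @export
transfer_entropy_ksg <- function(x, y, emb = embedding_spec()) {
  stopifnot(inherits(emb, "embedding_spec"))
  n <- length(x)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  if (n <= max(emb$d_x, emb$d_y) + emb$u + emb$K)
    stop("sequence too short for embedding", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in input", call. = FALSE)
  parts <- te_embed(rank_normalize(x), rank_normalize(y), emb)
  ksg_te_cpp(parts$yf, parts$yp, parts$xp, emb$K)
}

# Build the (y_{t+u}, y_t^{d_y}, x_t^{d_x}) matrices on the common t range.
te_embed <- function(zx, zy, emb) {
  n <- length(zx)
  d0 <- max(emb$d_x, emb$d_y)
  t_idx <- d0:(n - emb$u)               # embedding endpoint times
  yp <- delay_embed(zy, emb$d_y)[t_idx - emb$d_y + 1L, , drop = FALSE]
  xp <- delay_embed(zx, emb$d_x)[t_idx - emb$d_x + 1L, , drop = FALSE]
  list(yf = zy[t_idx + emb$u], yp = yp, xp = xp)
}

#' Transfer entropy with shuffled-vector surrogates
#'
#' The surrogate null shuffles the source's embedded past vectors
#' `x_t^{d_x}` as whole rows across time, preserving the target's own
#' predictability `p(y_{t+u} | y_t^{d_y})` while destroying any
#' cross-conditioning on the source.  The empirical p-value is the
#' `(r + 1) / (n_surr + 1)` rank of the real TE in the surrogate ensemble.
#'
#' @inheritParams transfer_entropy_ksg
#' @param n_surr number of surrogates (default 100; fewer than 20 gives a
#'   coarse p resolution and triggers a warning).
#' @param seed integer seed for the shuffles.
#' @return list of class `te_result`: `te` (nats), `embedding`,
#'   `surrogate_values`, `p_value`.
#' @export
te_with_surrogates <- function(x, y, emb = embedding_spec(), n_surr = 100L,
                               seed = 1L) {
  if (n_surr < 20L) warning("n_surr < 20: coarse p-value resolution")
  set.seed(seed)
  parts <- te_embed(rank_normalize(x), rank_normalize(y), emb)
  te <- ksg_te_cpp(parts$yf, parts$yp, parts$xp, emb$K)
  m <- length(parts$yf)
  surr <- vapply(seq_len(n_surr), function(i) {
    perm <- sample.int(m)
    ksg_te_cpp(parts$yf, parts$yp, parts$xp[perm, , drop = FALSE], emb$K)
  }, numeric(1))
  p <- (sum(surr >= te) + 1) / (n_surr + 1)
  structure(list(te = te, embedding = emb, surrogate_values = surr,
                 p_value = p),
            class = "te_result")
}

#' Windowed transfer entropy between smoothed MAP and a band power
#'
#' Per evaluable moving window, selects embedding dimensions for each
#' stream by [select_embedding()] and estimates TE in both directions.
#'
#' @inheritParams windowed_ami
#' @param d_max maximum embedding dimension (default 5).
#' @param K nearest neighbours (default 4).
#' @param thin keep every `thin`-th sample inside the window before
#'   estimation (default 1 = no thinning); the KSG search is quadratic in
#'   window length.
#' @return coupling series data.frame with measures `te_x_to_y`
#'   (MAP -> EEG) and `te_y_to_x` (EEG -> MAP) and columns `d_x`, `d_y`,
#'   `u`, `K`.
#' @export
windowed_te <- function(pair, band, win = window_spec(), d_max = 5L,
                        K = 4L, thin = 1L) {
  res <- list()
  for (dir in c("te_x_to_y", "te_y_to_x")) {
    rows <- eval_windows(pair, band, win, measure = dir, function(m, p) {
      if (thin > 1L) {
        keep <- seq(1L, length(m), by = thin)
        m <- m[keep]; p <- p[keep]
      }
      if (sd(m) == 0 || sd(p) == 0) return(NA_real_)
      src <- if (dir == "te_x_to_y") m else p
      tgt <- if (dir == "te_x_to_y") p else m
      dx <- as.integer(select_embedding(src, d_max, K))
      dy <- as.integer(select_embedding(tgt, d_max, K))
      transfer_entropy_ksg(src, tgt, embedding_spec(dx, dy, 1L, K))
    })
    res[[dir]] <- rows
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$K <- as.integer(K)
  out
}
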