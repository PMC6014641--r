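test_that("integer-range MAP quantization follows the mmHg rule", {
  q1 <- quantize_map(seq(31.2, 35.8, length.out = 50))
  expect_equal(attr(q1, "n_labels"), 5L)           # spans 31..35 mmHg
  q2 <- quantize_map(rep(40, 10))
  expect_equal(attr(q2, "n_labels"), 1L)           # constant window
  q3 <- quantize_map(c(30.1, 30.9, 31.5))
  expect_equal(attr(q3, "n_labels"), 2L)
  expect_equal(as.integer(q3), c(0L, 0L, 1L))
})

test_that("equal-width power quantization matches histogram edges", {
  ramp <- seq(0, 35 - 1e-9, length.out = 35) + 0.5
  q <- quantize_power(ramp, 35)
  expect_equal(as.integer(q), 0:34)                # uniform fill
  expect_equal(as.integer(quantize_power(ramp, 1)), rep(0L, 35))
  set.seed(5)
  v <- rnorm(200)
  q2 <- quantize_power(v, 12)
  edges <- seq(min(v), max(v), length.out = 13)
  oracle <- pmin(findInterval(v, edges, rightmost.closed = TRUE) - 1L, 11L)
  expect_equal(as.integer(q2), oracle)
})

test_that("plug-in MI matches identities and term-by-term summation", {
  x <- rep(0:3, 25)
  expect_equal(mutual_information(x, x), 2)        # log2(4) bits
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  set.seed(6)
  a <- sample(0:4, 50, replace = TRUE)
  b <- sample(0:3, 50, replace = TRUE)
  expect_equal(mutual_information(a, b), oracle_mi(a, b), tolerance = 1e-12)
  expect_error(mutual_information(a, b[1:10]))
  # bounds: 0 <= MI <= min(H(X), H(Y))
  hx <- -sum((table(a) / 50) * log2(table(a) / 50))
  hy <- -sum((table(b) / 50) * log2(table(b) / 50))
  expect_gte(mutual_information(a, b), 0)
  expect_lte(mutual_information(a, b), min(hx, hy) + 1e-12)
})

test_that("expected MI equals the exhaustive permutation mean", {
  # single X label: no X entropy, expectation 0
  expect_equal(expected_mi(6L, c(3L, 3L), 6L), 0)
  # 2x2 margins (2,2)/(2,2), N = 4: all 4! permutations
  x <- c(0L, 0L, 1L, 1L)
  ct <- contingency(x, x)
  expect_equal(expected_mi(ct$a_x, ct$b_y, 4L), oracle_perm_mean_mi(x, x),
               tolerance = 1e-12)
  # N = 7 with unequal 3-label margins, exhaustively
  set.seed(2)
  a <- c(0L, 0L, 0L, 1L, 1L, 2L, 2L)
  b <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L)
  ct2 <- contingency(a, b)
  expect_equal(expected_mi(ct2$a_x, ct2$b_y, 7L), oracle_perm_mean_mi(a, b),
               tolerance = 1e-12)
  expect_error(expected_mi(c(3L, 3L), c(2L, 2L), 6L), "inconsistent")
})

test_that("expected MI matches a Monte-Carlo permutation mean at N = 100", {
  set.seed(14)
  x <- sample(0:4, 100, replace = TRUE)
  y <- sample(0:4, 100, replace = TRUE)
  ct <- contingency(x, y)
  analytic <- expected_mi(ct$a_x, ct$b_y, 100L)
  mc <- vapply(seq_len(2000), function(i) mutual_information(x, sample(y)),
               numeric(1))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(analytic - mean(mc)), 3 * se)
})

test_that("AMI axioms: identity, symmetry, label-permutation invariance", {
  set.seed(15)
  x <- sample(0:4, 300, replace = TRUE)
  y <- sample(0:6, 300, replace = TRUE)
  expect_equal(adjusted_mi(x, x), 1)
  expect_equal(adjusted_mi(x, y), adjusted_mi(y, x), tolerance = 1e-9)
  relab <- c(4L, 2L, 0L, 1L, 3L)[x + 1L]          # permute label identities
  expect_equal(adjusted_mi(relab, y), adjusted_mi(x, y), tolerance = 1e-9)
  expect_lte(adjusted_mi(x, y), 1)
  expect_error(adjusted_mi(rep(1L, 10), rep(2L, 10)), "constant")
})

test_that("AMI agrees with the scikit-learn reference implementation", {
  set.seed(16)
  x <- sample(0:5, 100, replace = TRUE)
  y <- as.integer((x + sample(0:3, 100, replace = TRUE)) %% 7)
  ours <- adjusted_mi(x, y)
  script <- sprintf(
    "from sklearn.metrics import adjusted_mutual_info_score; print(repr(adjusted_mutual_info_score([%s], [%s], average_method='max')))",
    paste(x, collapse = ","), paste(y, collapse = ","))
  ref <- suppressWarnings(
    try(system2("python", c("-c", shQuote(script)), stdout = TRUE),
        silent = TRUE))
  if (inherits(ref, "try-error") || length(ref) == 0) {
    succeed("reference interpreter unavailable; covered by exact oracles")
  } else {
    expect_equal(ours, as.numeric(ref[length(ref)]), tolerance = 1e-9)
  }
})

test_that("AMI stays flat in label count on shuffled data, MI does not", {
  set.seed(17)
  n <- 1800
  a <- rnorm(n); b <- rnorm(n)
  mean_by_labels <- function(L, n_shuffle = 100) {
    qa <- quantize_power(a, L); qb <- quantize_power(b, L)
    ami <- mi <- numeric(n_shuffle)
    for (i in seq_len(n_shuffle)) {
      qs <- sample(as.integer(qb))
      ami[i] <- adjusted_mi(qa, new_ls(qs, L))
      mi[i] <- mutual_information(qa, new_ls(qs, L))
    }
    c(ami = mean(ami), mi = mean(mi))
  }
  new_ls <- function(l, L) structure(l, n_labels = as.integer(L),
                                     class = "label_seq")
  res <- vapply(c(5L, 20L, 50L), mean_by_labels, numeric(2))
  expect_true(all(abs(res["ami", ]) < 0.01))
  # raw MI inflates monotonically with label count on pure chance
  expect_true(all(diff(res["mi", ]) > 0))
})

test_that("bin-count selection recovers a planted granularity", {
  set.seed(18)
  planted <- 12L
  corpus <- lapply(1:3, function(s) {
    lapply(1:4, function(w) {
      m <- 35 + 4 * eegbp:::slow_process(900)
      lev <- as.integer(cut(m, planted))          # latent 12-level link
      power <- lev + 0.05 * rnorm(900)
      list(map = m, power = power)
    })
  })
  cand <- c(2L, 5L, 8L, 12L, 16L, 25L, 40L, 70L)
  sel <- select_n_bins(corpus, cand)
  expect_lte(abs(sel - planted), 5L)
  expect_equal(select_n_bins(corpus, 35L), 35L)   # single candidate
  expect_error(select_n_bins(list(), 1:3), "empty")
  # AMI-vs-bins profile decreases after its peak on this corpus
  grand <- vapply(cand, function(nb) {
    mean(vapply(corpus, function(subj) {
      mean(vapply(subj, function(w)
        adjusted_mi(quantize_map(w$map), quantize_power(w$power, nb)),
        numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  pk <- which.max(grand)
  if (pk < length(grand))
    expect_true(all(diff(grand[pk:length(grand)]) < 0))
})

test_that("windowed AMI detects nonlinear coupling and not independence", {
  set.seed(19)
  n <- 3600
  m <- 35 + 4 * eegbp:::slow_process(n)
  win <- window_spec(1800L, 900L)
  # strictly monotone (nonlinear) link: AMI high
  p_mono <- make_pair(n, m, m^3)
  ami_mono <- windowed_ami(p_mono, 1, win)
  expect_true(all(ami_mono$value > 0.5))
  # independent slow processes: AMI centred near zero (a small positive
  # offset is expected — autocorrelation shrinks the effective sample)
  vals <- replicate(15, {
    m2 <- 35 + 4 * eegbp:::slow_process(1800)
    p2 <- exp(0.4 * eegbp:::slow_process(1800))
    adjusted_mi(quantize_map(m2), quantize_power(p2, 35))
  })
  expect_lt(abs(mean(vals)), 0.1)
  # constant-MAP window is skipped
  p_const <- make_pair(n, rep(40, n), rep(1, n))
  expect_equal(nrow(windowed_ami(p_const, 1, win)), 0)
})
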