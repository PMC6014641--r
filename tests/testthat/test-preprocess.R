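make_sine_eeg <- function(freq, fs = 256, dur_s = 20, amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  eeg_record(matrix(rep(amp * sin(2 * pi * freq * t), 8), ncol = 8), fs = fs)
}

test_that("filter_and_downsample decimates and band-limits", {
  eeg <- make_sine_eeg(10, dur_s = 20)
  out <- filter_and_downsample(eeg)
  expect_equal(out$fs, 64)
  expect_equal(nrow(out$samples), 64 * 20)
  # 10 Hz is mid-band: amplitude preserved within 5% (trim filter edges)
  mid <- out$samples[200:1000, 1]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)
  # 50 Hz mains is outside the 0.3-30 Hz band: attenuated >= 40 dB
  mains <- filter_and_downsample(make_sine_eeg(50, dur_s = 20))
  p_in <- mean(make_sine_eeg(50)$samples[, 1]^2)
  p_out <- mean(mains$samples[200:1000, 1]^2)
  expect_gt(10 * log10(p_in / p_out), 40)
  # 1024 Hz input decimates by 16
  hi <- make_sine_eeg(10, fs = 1024, dur_s = 5)
  expect_equal(nrow(filter_and_downsample(hi)$samples), 64 * 5)
  bad <- make_sine_eeg(10); bad$fs <- 200
  expect_error(filter_and_downsample(bad), "unsupported")
})

test_that("amplitude thresholding flags flat and high-amplitude seconds", {
  set.seed(4)
  fs <- 256
  base <- matrix(rnorm(fs * 10 * 8, sd = 20), ncol = 8)
  base[(2 * fs + 1):(3 * fs), 3] <- 0                 # flat second, ch 3
  base[(5 * fs + 1):(6 * fs), 7] <- 1000              # burst second, ch 7
  v <- mark_eeg_artifacts(eeg_record(base, fs), amp_thresh_uV = 250)
  expect_false(v[3, 3])
  expect_false(v[6, 7])
  v[3, 3] <- TRUE; v[6, 7] <- TRUE
  expect_true(all(v))                                  # rest is clean
  expect_error(mark_eeg_artifacts(eeg_record(base, fs), amp_thresh_uV = -1))
})

test_that("band power concentrates, integrates exactly, and is robust", {
  # pure 2 Hz tone: >= 95% of band power in band 1
  t <- seq(0, 70 - 1 / 64, by = 1 / 64)
  tone <- eeg_record(matrix(rep(sin(2 * pi * 2 * t), 8), ncol = 8), fs = 64)
  fs64 <- extract_band_power(tone)
  bp <- fs64$band_power[1, ]
  expect_gt(bp[1] / sum(bp), 0.95)
  # Parseval: sum of the four band powers <= total 0.3-30 Hz power, and the
  # band integral equals a direct bin summation oracle to 1e-9 relative
  set.seed(11)
  noise <- matrix(rep(rnorm(64 * 70, sd = 10), 8), ncol = 8)
  fsn <- extract_band_power(eeg_record(noise, fs = 64))
  epoch <- noise[1:(60 * 64), 1]
  nfft <- length(epoch)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nfft - 1) / (nfft - 1)))
  sp <- Mod(fft((epoch - mean(epoch)) * w))^2 / (64 * sum(w^2))
  f <- (seq_len(nfft) - 1) * 64 / nfft
  half <- nfft %/% 2
  one_sided <- sp[1:(half + 1)]
  one_sided[2:half] <- 2 * one_sided[2:half]
  fo <- f[1:(half + 1)]
  direct <- sum(one_sided[fo >= 0.3 & fo < 3]) * (64 / nfft)
  expect_equal(fsn$band_power[1, 1], direct, tolerance = 1e-9)
  total <- sum(one_sided[fo >= 0.3 & fo <= 30]) * (64 / nfft)
  expect_lte(sum(fsn$band_power[1, ]), total * (1 + 1e-9))
  # 7 identical channels + 1 huge-artifact channel: the even-count median
  # (mean of the two central values) still equals the clean-channel value
  art <- noise
  art[, 8] <- art[, 8] * 100
  fsa <- extract_band_power(eeg_record(art, fs = 64))
  expect_equal(fsa$band_power[1, 1], fsn$band_power[1, 1],
               tolerance = 1e-9)
  # epochs with < 4 valid channels are invalid
  vs <- matrix(TRUE, 70, 8); vs[30, 1:5] <- FALSE
  fsv <- extract_band_power(eeg_record(noise, fs = 64), valid_sec = vs)
  expect_false(all(fsv$valid))
  short <- eeg_record(noise[1:(30 * 64), ], fs = 64)
  expect_error(extract_band_power(short), "shorter")
})

test_that("MAP formula and physiologic validity", {
  bp <- compute_map(0:2, sp = c(50, 60, 20), dp = c(50, 30, 40))
  expect_equal(bp$map[1], 50)          # sp = dp
  expect_equal(bp$map[2], 40)          # dp + (sp - dp)/3
  expect_false(bp$valid[3])            # sp < dp impossible
  expect_true(all(bp$dp[bp$valid] <= bp$map[bp$valid]))
  expect_true(all(bp$map[bp$valid] <= bp$sp[bp$valid]))
})

test_that("BP cleaning removes dropouts, outliers and interventions", {
  n <- 2 * 3600
  sp <- rep(48, n); dp <- rep(30, n)           # map = 36
  sp[100] <- 6; dp[100] <- 3                   # map 4 < 10 mmHg
  sp[200] <- 200; dp[200] <- 150               # sharp outlier
  bp <- compute_map(0:(n - 1), sp, dp)
  cl <- clean_bp(bp, interventions = 3600)
  expect_false(cl$valid[100])     # position 100 holds the injected dropout
  expect_false(cl$valid[200])     # position 200 holds the sharp outlier
  # 10 min either side of the intervention at t = 3600
  expect_false(any(cl$valid[(3000:4200) + 1]))
  expect_true(cl$valid[2999 + 1])
  expect_true(cl$valid[4202 + 1])
  rep_ <- attr(cl, "report")
  expect_equal(rep_$low_bp, 1L)
  # constant series: outlier rule removes nothing
  bp2 <- compute_map(0:999, rep(48, 1000), rep(30, 1000))
  expect_true(all(clean_bp(bp2)$valid))
})

test_that("synchronization smooths MAP and intersects masks", {
  n <- 400
  feats <- structure(list(time_s = 0:(n - 61),
                          band_power = matrix(1, n - 60, 4),
                          valid = rep(TRUE, n - 60)),
                     class = "feature_series")
  feats$valid[10] <- FALSE
  bp <- compute_map(0:(n - 1), rep(48, n), rep(30, n))
  pair <- synchronize(feats, bp)
  expect_s3_class(pair, "aligned_pair")
  expect_true(all(pair$map_smoothed == 36))    # constant stays constant
  expect_false(pair$valid[10])                 # EEG-invalid second removed
  # step 30 -> 50 mmHg: smoothed value at the step stays within [30, 50]
  mapv <- c(rep(30, 200), rep(50, 200))
  bp2 <- compute_map(0:(n - 1), mapv + 10, mapv - 5)  # map = mapv
  pair2 <- synchronize(feats, bp2)
  i <- which(pair2$time_s == 170)
  expect_true(all(pair2$map_smoothed >= 30 - 1e-9 &
                    pair2$map_smoothed <= 50 + 1e-9))
  expect_gt(pair2$map_smoothed[which(pair2$time_s == 199)], 30)
  bp3 <- compute_map(5000:5999, rep(48, 1000), rep(30, 1000))
  expect_error(synchronize(feats, bp3), "overlap")
})

test_that("injected artifacts are invalidated, clean data preserved", {
  rec <- gen_synthetic_recording(0.25, coupling = 0.5, seed = 13,
                                 artifacts = TRUE)
  v <- mark_eeg_artifacts(rec$eeg)
  all_bad <- sort(union(rec$truth$flat_sec, rec$truth$burst_sec)) + 1L
  sec_invalid <- rowSums(!v) > 4                # artifact hits all channels
  expect_gte(mean(sec_invalid[all_bad]), 0.95)
  clean <- setdiff(seq_len(nrow(v)), all_bad)
  expect_lte(mean(sec_invalid[clean]), 0.05)
  # preprocessing is deterministic end to end
  p1 <- preprocess_recording(rec)
  p2 <- preprocess_recording(rec)
  expect_identical(p1$band_power, p2$band_power)
  expect_identical(p1$valid, p2$valid)
  expect_true(all(is.finite(p1$band_power[p1$valid, ])))
  expect_true(all(p1$band_power[p1$valid, ] >= 0))
})

test_that("YAML preprocessing config merges over defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("amp_thresh_uV: 300", "min_mmHg: 12"), path)
  cfg <- preprocess_config(path)
  expect_equal(cfg$amp_thresh_uV, 300)
  expect_equal(cfg$min_mmHg, 12)
  expect_equal(cfg$epoch_s, 60L)
})
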