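test_that("noiseless step onsets are recovered exactly with zero SE", {
  nt <- 150
  times <- seq(-200, by = 4, length.out = nt)
  step <- ifelse(times >= 120, 5, 0)
  D <- matrix(rep(step, each = 9), 9)
  est <- jackknife_onset(D, rate_hz = 250, t0_ms = -200)
  expect_true(est$complete)
  expect_true(all(est$subsample_latencies_ms == 120))
  expect_identical(est$mean_ms, 120)
  expect_identical(est$corrected_se_ms, 0)
  expect_identical(est$n, 9L)
})

test_that("corrected SE inflates the subsample SD by (n-1)/sqrt(n)", {
  nt <- 150
  times <- seq(-200, by = 4, length.out = nt)
  # leave-one-out averages cross at slightly different samples
  D <- t(sapply(1:8, function(s)
    ifelse(times >= 120, 5, 0) + ifelse(times >= 100, (s - 4.5) * 0.8, 0)))
  est <- jackknife_onset(D, rate_hz = 250, t0_ms = -200)
  expect_true(est$complete)
  expect_equal(est$corrected_se_ms,
               stats::sd(est$subsample_latencies_ms) * 7 / sqrt(8))
})

test_that("a flat difference waveform is flagged incomplete", {
  D <- matrix(0, 6, 100)
  est <- jackknife_onset(D, rate_hz = 250, t0_ms = -200)
  expect_false(est$complete)
  expect_true(all(is.na(est$subsample_latencies_ms)))
  expect_true(is.na(est$mean_ms))
  other <- jackknife_onset(matrix(rep(c(rep(0, 60), rep(9, 40)), each = 6), 6),
                           rate_hz = 250, t0_ms = -200)
  expect_error(jackknife_two_sample_test(est, other), "complete")
})

test_that("jackknife-adjusted group test behaves at the extremes", {
  nt <- 150
  times <- seq(-200, by = 4, length.out = nt)
  mk <- function(onset, n, wobble = 0) t(sapply(seq_len(n), function(s)
    ifelse(times >= onset, 5, 0) +
      ifelse(times >= onset - 20, wobble * (s %% 2), 0)))
  a <- jackknife_onset(mk(100, 9), rate_hz = 250, t0_ms = -200)
  b <- jackknife_onset(mk(100, 9), rate_hz = 250, t0_ms = -200)
  same <- jackknife_two_sample_test(a, b)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_identical(same$df, 16)
  # degenerate: zero variance but different means -> flagged infinite t
  c2 <- jackknife_onset(mk(180, 8), rate_hz = 250, t0_ms = -200)
  degen <- jackknife_two_sample_test(a, c2)
  expect_true(degen$degenerate)
  expect_true(is.infinite(degen$t))
  expect_identical(degen$p, 0)
  # with subsample variability, a clear onset difference is significant
  mk2 <- function(onset, n) t(sapply(seq_len(n), function(s)
    ifelse(times >= onset + 4 * (s - (n + 1) / 2), 5, 0)))
  a2 <- jackknife_onset(mk2(100, 9), rate_hz = 250, t0_ms = -200)
  b2 <- jackknife_onset(mk2(180, 9), rate_hz = 250, t0_ms = -200)
  expect_gt(a2$corrected_se_ms, 0)
  test <- jackknife_two_sample_test(a2, b2)
  expect_false(test$degenerate)
  expect_lt(test$p, 0.05)
  expect_lt(test$t, 0)
})

test_that("channel-subset means preserve polarity and partition the array", {
  set.seed(30)
  n_ch <- 20; nt <- 100
  times <- seq(-200, by = 4, length.out = nt)
  dip <- c(rep(1, 10), rep(-1, 10))
  bump <- exp(-(times - 90)^2 / (2 * 17^2))
  evs <- lapply(1:6, function(s) dip %o% (bump * (1 + 0.1 * s)))
  res <- channel_subset_means(evs, window_ms = c(72, 112), n_select = 10,
                              rate_hz = 250, t0_ms = -200)
  # perfectly antisymmetric evoked: positive mean = -(negative mean)
  expect_equal(res$positive, -res$negative, tolerance = 1e-12)
  expect_length(intersect(res$positive_channels, res$negative_channels), 0)
  expect_setequal(c(res$positive_channels, res$negative_channels), 1:20)
  # planted gain appears with its sign preserved
  expect_gt(max(res$positive[6, ]), max(res$positive[1, ]))
  expect_error(channel_subset_means(evs, c(72, 112), n_select = 11,
                                    rate_hz = 250, t0_ms = -200), "half")
  expect_error(channel_subset_means(evs, c(900, 950), n_select = 5,
                                    rate_hz = 250, t0_ms = -200), "window")
})
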