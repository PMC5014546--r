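test_that("RMS summarises sensors as stated", {
  expect_equal(rms_timecourse(matrix(c(3, 4), 2, 1), 250, 0)$values,
               sqrt(12.5))
  expect_equal(rms_timecourse(matrix(-5, 1, 3), 250, 0)$values, rep(5, 3))
  ev <- structure(list(data = matrix(0, 4, 10), rate_hz = 250, t0_ms = -40),
                  class = "evoked_response")
  expect_true(all(rms_timecourse(ev)$values == 0))
})

test_that("identical conditions yield no clusters", {
  set.seed(2)
  A <- matrix(stats::rnorm(8 * 50), 8)
  res <- cluster_permutation_test(A, A, "paired", n_perm = 200, seed = 1,
                                  rate_hz = 250, t0_ms = 0)
  expect_identical(nrow(res$clusters), 0L)
})

test_that("a planted sustained difference produces a significant cluster", {
  set.seed(3)
  n <- 12; nt <- 100
  times <- (seq_len(nt) - 1) * 4
  effect <- 2.5 * (times >= 200)
  A <- matrix(stats::rnorm(n * nt), n) + rep(effect, each = n)
  B <- matrix(stats::rnorm(n * nt), n)
  res <- cluster_permutation_test(A, B, "paired", n_perm = 500, seed = 4,
                                  rate_hz = 250, t0_ms = 0)
  sig <- res$clusters[res$clusters$fwe_p < 0.05, ]
  expect_gt(nrow(sig), 0)
  # the dominant cluster covers the injected onset region
  top <- sig[which.max(sig$cluster_stat), ]
  expect_lt(top$start_ms, 230)
  expect_gt(top$end_ms, 300)
})

test_that("permutation p-values are stable in the permutation count", {
  set.seed(6)
  n <- 10; nt <- 60
  A <- matrix(stats::rnorm(n * nt), n) +
    rep(c(rep(0, 20), rep(0.9, 20), rep(0, 20)), each = n)
  B <- matrix(stats::rnorm(n * nt), n)
  p1 <- cluster_permutation_test(A, B, "paired", n_perm = 1000, seed = 7,
                                 rate_hz = 250, t0_ms = 0)$clusters$fwe_p[1]
  p2 <- cluster_permutation_test(A, B, "paired", n_perm = 2000, seed = 8,
                                 rate_hz = 250, t0_ms = 0)$clusters$fwe_p[1]
  mc_se <- sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(p1 - p2), 4 * mc_se + 2e-3)
})

test_that("max cluster mass grows monotonically with the planted effect", {
  set.seed(9)
  n <- 10; nt <- 80
  noiseA <- matrix(stats::rnorm(n * nt), n)
  noiseB <- matrix(stats::rnorm(n * nt), n)
  shape <- rep(c(rep(0, 30), rep(1, 30), rep(0, 20)), each = n)
  maxstat <- vapply(c(0, 0.5, 1, 2, 4), function(g) {
    res <- cluster_permutation_test(noiseA + g * shape, noiseB, "paired",
                                    n_perm = 200, seed = 10,
                                    rate_hz = 250, t0_ms = 0)
    if (nrow(res$clusters)) max(res$clusters$cluster_stat) else 0
  }, numeric(1))
  expect_true(all(diff(maxstat) >= 0))
})

test_that("two-sample design detects group differences", {
  set.seed(12)
  A <- matrix(stats::rnorm(9 * 60), 9) +
    rep(c(rep(0, 20), rep(1.2, 25), rep(0, 15)), each = 9)
  B <- matrix(stats::rnorm(8 * 60), 8)
  res <- cluster_permutation_test(A, B, "two_sample", n_perm = 500,
                                  seed = 13, rate_hz = 250, t0_ms = 0)
  expect_true(any(res$clusters$fwe_p < 0.05))
  expect_error(cluster_permutation_test(A[1:2, ], B[1:2, ], "paired",
                                        rate_hz = 250, t0_ms = 0),
               "subject")
})

test_that("exhaustive sign-flip enumeration matches an independent oracle", {
  set.seed(20)
  n <- 8; nt <- 30
  A <- matrix(stats::rnorm(n * nt), n) +
    rep(c(rep(0, 10), rep(0.8, 10), rep(0, 10)), each = n)
  B <- matrix(stats::rnorm(n * nt), n)
  res <- cluster_permutation_test(A, B, "paired", height_p = 0.05,
                                  method = "exhaustive",
                                  rate_hz = 250, t0_ms = 0)
  expect_identical(res$n_perm, 256L)
  # independent oracle: direct t-statistics over all 2^8 sign patterns
  D <- A - B
  thr <- stats::qt(0.975, n - 1)
  oracle_max <- function(signs) {
    S <- D * signs
    tv <- apply(S, 2, function(col) mean(col) / (stats::sd(col) / sqrt(n)))
    supra <- abs(tv) > thr
    if (!any(supra)) return(0)
    r <- rle(supra)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    max(vapply(which(r$values),
               function(i) sum(abs(tv[starts[i]:ends[i]])), numeric(1)))
  }
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_oracle <- apply(grid, 1, oracle_max)
  expect_equal(sort(res$null_max), sort(null_oracle), tolerance = 1e-10)
  # and the Monte-Carlo p agrees with the exact one within sampling error
  obs_stat <- max(res$clusters$cluster_stat)
  p_exact <- mean(null_oracle >= obs_stat)
  mc <- cluster_permutation_test(A, B, "paired", n_perm = 2000, seed = 21,
                                 rate_hz = 250, t0_ms = 0)
  p_mc <- mc$clusters$fwe_p[which.max(mc$clusters$cluster_stat)]
  expect_lt(abs(p_mc - p_exact),
            4 * sqrt(max(p_exact, 0.01) * (1 - p_exact) / 2000) + 2e-3)
})
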