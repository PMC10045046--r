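test_that("Z-score normalization standardizes then lands in [0, 1]", {
  expect_equal(zscoreNormalize(c(0, 1, 2)), c(0, 0.5, 1))
  const <- matrix(7, 4, 4)
  expect_equal(zscoreNormalize(const), matrix(0.5, 4, 4))
  set.seed(2)
  x <- matrix(rnorm(64, 100, 20), 8, 8)
  y <- zscoreNormalize(x)
  expect_equal(min(y), 0); expect_equal(max(y), 1)
  # invariance to positive affine transforms of the input
  expect_equal(zscoreNormalize(3.7 * x + 12), y, tolerance = 1e-12)
  expect_error(zscoreNormalize(numeric(0)), "empty")
})

test_that("frame histograms are normalized equal-width bins", {
  h <- frameHistogram(matrix(5, 3, 3), nBins = 16)
  expect_equal(sum(h$probs), 1)
  expect_equal(max(h$probs), 1)  # constant frame: one bin holds all mass
  h2 <- frameHistogram(c(rep(0, 5), rep(1, 5)), nBins = 2, range = c(0, 1))
  expect_equal(h2$probs, c(0.5, 0.5))  # upper bound falls in the last bin
  set.seed(1)
  h3 <- frameHistogram(runif(1000), nBins = 64)
  expect_equal(sum(h3$probs), 1, tolerance = 1e-9)
  expect_error(frameHistogram(c(1, 2), range = c(5, 6)), "outside")
})

test_that("relative entropy matches hand-computed values and stays >= 0", {
  same <- relativeEntropy(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$dRE, 0); expect_equal(same$dSRRE, 0)
  d <- relativeEntropy(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(d$dRE, 0.5 * log2(2) + 0.5 * log2(2 / 3), tolerance = 1e-12)
  expect_equal(d$dRE, 0.20752, tolerance = 1e-4)
  expect_equal(d$dSRRE, sqrt(d$dRE))
  expect_equal(d$dSRRE, 0.45554, tolerance = 1e-4)
  expect_error(relativeEntropy(c(0.5, 0.5), c(1, 0, 0)), "mismatch")
  # KL non-negativity over random histogram pairs (with zero bins)
  set.seed(7)
  for (i in seq_len(1000)) {
    p <- runif(16); p[sample(16, 3)] <- 0; p <- p / sum(p)
    q <- runif(16); q[sample(16, 3)] <- 0; q <- q / sum(q)
    expect_gte(relativeEntropy(p, q)$dRE, 0)
  }
})

test_that("redundant-frame elimination collapses near-duplicates", {
  base <- matrix(seq(0, 1, length.out = 64), 8, 8)
  other <- matrix(rep(c(0, 1), 32), 8, 8)
  expect_equal(eliminateRedundantFrames(rep(list(base), 6), 0.01), 1L)
  # alternating very different frames with a small threshold: all kept
  alt <- rep(list(base, other), 3)
  expect_equal(eliminateRedundantFrames(alt, 0.01), 1:6)
  # [A, A + tiny noise, B] with a threshold between the two distances
  tiny <- base + matrix(rnorm(64, 0, 1e-3), 8, 8)
  rng <- range(c(base, tiny, other))
  dNear <- relativeEntropy(frameHistogram(base, range = rng),
                           frameHistogram(tiny, range = rng))$dRE
  dFar <- relativeEntropy(frameHistogram(base, range = rng),
                          frameHistogram(other, range = rng))$dRE
  thr <- (dNear + dFar) / 2
  expect_equal(eliminateRedundantFrames(list(base, tiny, other), thr),
               c(1L, 3L))
  expect_error(eliminateRedundantFrames(list(base), -1), ">= 0")
})

test_that("frame filtering returns an idempotent subsequence", {
  set.seed(5)
  frames <- lapply(1:12, function(i)
    matrix(rnorm(64, mean = i %/% 4), 8, 8))
  kept <- eliminateRedundantFrames(frames, 0.05)
  expect_equal(kept[1], 1L)
  expect_true(all(diff(kept) > 0))
  # re-running on the kept frames keeps everything
  again <- eliminateRedundantFrames(frames[kept], 0.05)
  expect_equal(again, seq_along(kept))
})
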