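test_that("one-level wavelet transform is orthonormal and invertible", {
  set.seed(1)
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  sb <- waveletDecompose(x, "d8")
  expect_setequal(names(subbands(sb)),
                  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_equal(dim(subbands(sb)$LLL), c(8, 8, 8))
  expect_lt(max(abs(waveletReconstruct(sb) - x)), 1e-8)

  # Parseval: energy is conserved by the orthonormal filter bank
  eIn <- sum(x^2)
  eSb <- sum(vapply(subbands(sb), function(s) sum(s^2), 1))
  expect_lt(abs(eIn - eSb) / eIn, 1e-8)

  # 2-D path and odd-dimension padding round-trip exactly too
  m <- matrix(rnorm(18 * 14), 18, 14)
  expect_lt(max(abs(waveletReconstruct(waveletDecompose(m, "d8")) - m)), 1e-8)
  modd <- matrix(rnorm(17 * 15), 17, 15)
  sbo <- waveletDecompose(modd, "haar")
  expect_equal(dim(subbands(sbo)$LL), c(9, 8))  # ceiling of half
  expect_lt(max(abs(waveletReconstruct(sbo) - modd)), 1e-8)

  # a constant volume has all of its energy in the approximation band
  sbc <- waveletDecompose(array(5, dim = c(8, 8, 8)), "d8")
  detailMax <- max(vapply(subbands(sbc)[-1], function(s) max(abs(s)), 1))
  expect_lt(detailMax, 1e-10)

  expect_error(waveletDecompose(x, "sym9"), "unknown wavelet")
})

test_that("Bayesian threshold quantities follow the BayesShrink arithmetic", {
  # MAD scaling: median absolute finest-band coefficient 0.6745 -> sigmaN 1
  mk <- function(v) array(v, dim = c(2, 2, 2))
  sbl <- list(LLL = mk(10), LLH = mk(1), LHL = mk(1), LHH = mk(1),
              HLL = mk(1), HLH = mk(1), HHL = mk(1),
              HHH = mk(c(-0.6745, 0.6745)))
  sbs <- new("SubbandSet", subbands = sbl, waveletName = "haar",
             originalShape = c(4L, 4L, 4L))
  est <- estimateThreshold(sbs)
  expect_equal(est$HHH@sigmaN, 1.0, tolerance = 1e-12)

  # sigma_y^2 = 5, sigma_N^2 = 1 -> sigma_s = 2, T_B = 0.5
  bt <- bayesThreshold(sqrt(5), 1)
  expect_equal(bt$sigmaS, 2)
  expect_equal(bt$tB, 0.5)

  # pure-noise subband: sigma_y <= sigma_N clamps sigma_s to 0 and the
  # sentinel (max |coefficient|) shrinks everything
  sbl2 <- lapply(sbl, function(z) mk(c(-1, 1)))  # |median| = 1, rms = 1
  sbs2 <- new("SubbandSet", subbands = sbl2, waveletName = "haar",
              originalShape = c(4L, 4L, 4L))
  est2 <- estimateThreshold(sbs2)
  expect_equal(est2$LLH@sigmaS, 0)
  expect_true(est2$LLH@sentinel)
  expect_equal(est2$LLH@tB, 1)  # max |coefficient|
})

test_that("the curve-fitted modifier reproduces the printed coefficients", {
  expect_equal(gammaModifier(0), -0.138 / 0.1245, tolerance = 1e-12)
  expect_equal(gammaModifier(0), -1.10843, tolerance = 1e-5)
  expect_equal(gammaModifier(1), 4.4692 / 1.1245, tolerance = 1e-12)
  expect_equal(gammaModifier(1), 3.97439, tolerance = 1e-5)
  expect_equal(gammaModifier(0.7, p1 = 0, p2 = 0, p3 = 0), 0)
  expect_error(gammaModifier(-0.1245), "pole")
})

test_that("collaborative thresholding behaves at the edge cases", {
  set.seed(3)
  g <- matrix(rnorm(32 * 32), 32, 32)
  # zero threshold is a no-op (blocks reconstruct exactly, weights average)
  expect_lt(max(abs(collaborativeThreshold(g, 0, 1) - g)), 1e-8)
  # a constant grid passes through: only DC coefficients, never touched
  cg <- matrix(7, 16, 16)
  expect_lt(max(abs(collaborativeThreshold(cg, 5, 2) - 7)), 1e-10)
  # shrinkage never grows a coefficient (hard and soft)
  for (op in c("hard", "soft")) {
    v <- rnorm(200, 0, 3)
    out <- noduleCAD:::.shrinkCoeffs(v, 1.5, op)
    expect_true(all(abs(out) <= abs(v) + 1e-15))
  }
  expect_error(denoiseConfig(groupSize = 0), "groupSize")
  expect_error(denoiseConfig(q = 0), "q must")
})

test_that("the denoiser leaves clean slices alone and cleans noisy ones", {
  clean <- sampleImage(makePhantom(phantomSpec(noiseSigma = 0,
                                               spacingMm = 1)))
  den0 <- denoiseVolume(clean)
  expect_lt(mean((den0 - clean)^2) / mean(clean^2), 0.02)

  noisy <- addNoise(clean, 15, seed = 42)
  den <- denoiseVolume(noisy)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
  expect_gt(filteringAccuracy(clean, den), filteringAccuracy(clean, noisy))

  # near-idempotence: a second pass changes less than the first one gained
  den2 <- denoiseVolume(den)
  firstGain <- mean((noisy - clean)^2) - mean((den - clean)^2)
  expect_lt(abs(mean((den2 - clean)^2) - mean((den - clean)^2)), firstGain)

  # CtVolume in, CtVolume out
  dv <- denoiseVolume(ctVolume(noisy, 0.7))
  expect_s4_class(dv, "CtVolume")
  expect_equal(spacingMm(dv), 0.7)
})

test_that("filtering accuracy is the capped inverse MSE in percent", {
  a <- matrix(0, 4, 4)
  expect_equal(as.numeric(filteringAccuracy(a, a + 2)), 25)   # MSE 4
  expect_equal(as.numeric(filteringAccuracy(a, a + 1)), 100)  # MSE 1
  same <- filteringAccuracy(a, a)
  expect_true(attr(same, "exact"))
  expect_equal(as.numeric(same), 1e14)  # documented cap at MSE 1e-12
  expect_error(filteringAccuracy(a, matrix(0, 2, 2)), "shape")
})
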