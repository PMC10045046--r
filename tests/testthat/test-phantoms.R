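test_that("phantom geometry matches its spec", {
  s <- makePhantom(phantomSpec(noduleDiameterMm = 10, spacingMm = 1,
                               spiculationLevel = 0, noiseSigma = 0))
  # equivalent-circle diameter from the mask area
  d <- 2 * sqrt(sum(sampleMask(s)) / pi)
  expect_gt(d, 9); expect_lt(d, 11)

  # determinism: identical specs give bit-identical samples
  s2 <- makePhantom(phantomSpec(noduleDiameterMm = 10, spacingMm = 1,
                                spiculationLevel = 0, noiseSigma = 0))
  expect_identical(sampleImage(s), sampleImage(s2))
  expect_identical(sampleMask(s), sampleMask(s2))

  # spiculated boundary is longer at equal diameter (perimeter oracle on
  # both masks)
  sm <- makePhantom(phantomSpec(noduleDiameterMm = 12, spacingMm = 1,
                                spiculationLevel = 0, noiseSigma = 0,
                                noduleClass = "malignant"))
  sp <- makePhantom(phantomSpec(noduleDiameterMm = 12, spacingMm = 1,
                                spiculationLevel = 0.8, noiseSigma = 0,
                                noduleClass = "malignant"))
  expect_gt(shapeFeatures(sampleMask(sp))$perimeter,
            shapeFeatures(sampleMask(sm))$perimeter)

  # a nodule wider than the slice is rejected
  expect_error(makePhantom(phantomSpec(imageSize = 16, spacingMm = 1,
                                       noduleDiameterMm = 20)),
               "exceeds")
  expect_error(phantomSpec(spiculationLevel = 1.5), "0, 1")
})

test_that("additive noise has the stated scale and is reproducible", {
  img <- matrix(50, 64, 64)
  expect_identical(addNoise(img, 0), img)
  noisy <- addNoise(img, 10, seed = 4)
  res <- noisy - img
  expect_gt(sd(res), 8.5); expect_lt(sd(res), 11.5)
  expect_identical(addNoise(img, 10, seed = 4), noisy)
  expect_error(addNoise(img, -1), ">= 0")
  # residual is plausibly Gaussian: skewness and excess kurtosis near 0
  big <- addNoise(matrix(0, 100, 100), 5, seed = 9)
  z <- as.vector(big)
  m <- mean(z); s <- sd(z)
  expect_lt(abs(mean((z - m)^3) / s^3), 0.5)
  expect_lt(abs(mean((z - m)^4) / s^4 - 3), 0.5)
})

test_that("dataset generation honours balance, seeds and sensor model", {
  ds <- makeDataset(100, 0.5, imageSize = 32, diameterRangeMm = c(5, 10), noiseSigma = 0, seed = 2)
  expect_length(ds, 100)
  expect_equal(sum(vapply(ds, sampleLabel, "") == "malignant"), 50)
  ds2 <- makeDataset(10, 0.3, imageSize = 32, diameterRangeMm = c(5, 10), noiseSigma = 0, seed = 2)
  expect_equal(sum(vapply(ds2, sampleLabel, "") == "malignant"), 3)
  expect_error(makeDataset(1, 0.5), "n must be")
  expect_error(makeDataset(10, 0.01), "unsatisfiable")

  # extensibility: the first samples of a longer dataset are unchanged
  ds3 <- makeDataset(12, 0.5, imageSize = 32, diameterRangeMm = c(5, 10), noiseSigma = 0, seed = 2)
  expect_identical(sampleImage(ds3[[2]]),
                   sampleImage(makeDataset(4, 0.5, imageSize = 32,
                                           diameterRangeMm = c(5, 10),
                                           noiseSigma = 0,
                                           seed = 2)[[2]]))

  # class-conditional sensors: a midpoint threshold on one dimension
  # separates the classes with >= 90% accuracy at n = 200
  big <- makeDataset(200, 0.5, imageSize = 32, diameterRangeMm = c(5, 10), noiseSigma = 0,
                     sensorShift = 3, sensorSigma = 1, seed = 5)
  x1 <- vapply(big, function(s) sensorValues(s)[1], 1)
  lab <- vapply(big, sampleLabel, "")
  pred <- ifelse(x1 > 1.5, "malignant", "benign")
  expect_gte(mean(pred == lab), 0.9)
})

test_that("malignant masks are rougher than benign at matched draws", {
  ds <- makeDataset(60, 0.5, imageSize = 64, noiseSigma = 0, seed = 21)
  ratio <- vapply(ds, function(s) {
    sf <- shapeFeatures(s)
    sf$perimeter / sf$area
  }, 1)
  lab <- vapply(ds, sampleLabel, "")
  expect_gt(mean(ratio[lab == "malignant"]), mean(ratio[lab == "benign"]))
  # and per-pair ordering of the boundary irregularity is near-perfect
  circ <- vapply(ds, function(s) shapeFeatures(s)$circularity, 1)
  expect_gte(sum(circ[lab == "malignant"][1:30] <
                   circ[lab == "benign"][1:30]), 27)
})
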