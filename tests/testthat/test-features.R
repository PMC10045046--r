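test_that("GLCM construction matches direct pair enumeration", {
  # 2x2 image, one horizontal offset, asymmetric: two pairs on the diagonal
  g <- computeGlcm(matrix(c(0, 1, 0, 1), 2, 2), c(0, 1), nLevels = 2,
                   symmetric = FALSE)
  expect_equal(g$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(g$matrix), 1)
  # constant image: all mass at one diagonal cell
  gc <- computeGlcm(matrix(3, 4, 4), c(1, 0), nLevels = 8)
  expect_equal(gc$matrix[1, 1], 1)
  expect_error(computeGlcm(matrix(1, 3, 3), c(0, 0)), "nonzero")
  expect_error(computeGlcm(matrix(1, 3, 3), c(0, 5)), "larger")

  set.seed(11)
  for (i in 1:20) {
    img <- matrix(runif(16 * 16), 16, 16)
    for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      for (sym in c(TRUE, FALSE)) {
        expect_lt(max(abs(computeGlcm(img, off, 8, sym)$matrix -
                            bruteGlcm(img, off, 8, sym))), 1e-12)
      }
    }
  }
})

test_that("texture features agree with a double-loop oracle", {
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  tf <- textureFeatures(computeGlcm(cb, c(0, 1), nLevels = 2))
  expect_equal(tf$contrast, 1)  # every horizontal pair differs by 1 level
  tfc <- textureFeatures(computeGlcm(matrix(5, 6, 6), c(0, 1), nLevels = 8))
  expect_equal(tfc$contrast, 0)
  expect_equal(tfc$homogeneity, 1)
  expect_equal(tfc$entropy, 0)
  expect_true(is.na(tfc$correlation))  # zero marginal deviation marker

  set.seed(12)
  for (i in 1:25) {
    img <- matrix(runif(256), 16, 16)
    g <- computeGlcm(img, c(1, 1), nLevels = 8)
    got <- textureFeatures(g)
    want <- bruteTexture(g$matrix)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]],
                                         tolerance = 1e-10)
  }
})

test_that("shape features match closed forms and invariances", {
  # single pixel: area = pixel area, perimeter = pixel square
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  sf1 <- shapeFeatures(m1, spacingMm = 2)
  expect_equal(sf1$area, 4)       # 1 px * (2 mm)^2
  expect_equal(sf1$perimeter, 8)  # 4 * spacing
  expect_error(shapeFeatures(matrix(FALSE, 3, 3)), "empty")

  # digital squares converge on the continuous isoperimetric value pi/4;
  # at side n the corrected perimeter is 4(n - 1) + pi
  for (n in c(16, 64)) {
    sf <- shapeFeatures(mkSquare(n))
    expect_equal(sf$circularity, 4 * pi * n^2 / (4 * (n - 1) + pi)^2,
                 tolerance = 1e-10)
  }
  expect_lt(abs(shapeFeatures(mkSquare(200))$circularity - pi / 4), 0.01)

  # digital disk: roundness close to 1
  sfd <- shapeFeatures(mkDisk(20))
  expect_gt(sfd$roundness, 0.85); expect_lt(sfd$roundness, 1.1)
  expect_equal(sfd$aspectRatio, 1, tolerance = 0.05)

  # translation invariance of every shape feature
  mA <- matrix(FALSE, 40, 40); mA[8:20, 6:16] <- TRUE
  mB <- matrix(FALSE, 40, 40); mB[11:23, 11:21] <- TRUE
  expect_equal(shapeFeatures(mA), shapeFeatures(mB), tolerance = 1e-12)

  # scale behaviour: doubling the spacing quadruples area, doubles
  # perimeter and diameter, and leaves the ratios unchanged
  s1 <- shapeFeatures(mkDisk(12), spacingMm = 1)
  s2 <- shapeFeatures(mkDisk(12), spacingMm = 2)
  expect_equal(s2$area, 4 * s1$area)
  expect_equal(s2$perimeter, 2 * s1$perimeter)
  expect_equal(s2$circularity, s1$circularity)
  expect_equal(semanticFeatures(mkDisk(12), 2)$diameterMm,
               2 * semanticFeatures(mkDisk(12), 1)$diameterMm)

  # discrete masks may exceed the isoperimetric bound only slightly
  set.seed(3)
  for (i in 1:20) {
    ms <- sampleMask(makePhantom(phantomSpec(
      noduleDiameterMm = runif(1, 6, 16), spacingMm = 1,
      spiculationLevel = runif(1), noiseSigma = 0,
      noduleClass = "malignant", seed = i)))
    expect_lt(shapeFeatures(ms)$circularity, 1.15)
  }
})

test_that("intensity features are the moments of the masked histogram", {
  img <- matrix(c(0, 2), 4, 4)  # two equiprobable intensities {0, 2}
  msk <- matrix(TRUE, 4, 4)
  fi <- intensityFeatures(img, msk)
  expect_equal(fi$mean, 1)
  expect_equal(fi$variance, 1)
  expect_equal(fi$skewness, 0)
  expect_equal(fi$kurtosis, 1)
  expect_equal(fi$uniformity, 0.5)
  expect_equal(fi$smoothness, 0.5)  # 1 - 1/(1 + 1)

  one <- intensityFeatures(matrix(9, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(one$uniformity, 1)
  expect_equal(one$variance, 0)
  expect_equal(one$smoothness, 0)
  expect_error(intensityFeatures(img, matrix(FALSE, 4, 4)), "empty")
})

test_that("semantic attributes follow the size bins and morphology rules", {
  diamMask <- function(dMm) mkDisk(dMm / 2)
  expect_equal(semanticFeatures(diamMask(3.5), 1)$sizeBin, "<4 mm")
  expect_equal(semanticFeatures(diamMask(10), 1)$sizeBin, "8-20 mm")
  expect_equal(semanticFeatures(diamMask(24), 1)$sizeBin, ">20 mm")
  # boundary diameters go to the lower bin: a 16-px mask at spacing
  # sqrt(pi)/2 has area 4*pi mm^2, i.e. an equivalent diameter of
  # exactly 4 mm
  sq4 <- mkSquare(4)
  expect_equal(semanticFeatures(sq4, sqrt(pi) / 2)$diameterMm, 4)
  expect_equal(semanticFeatures(sq4, sqrt(pi) / 2)$sizeBin, "<4 mm")

  disk <- semanticFeatures(mkDisk(15), 1)
  expect_lt(disk$spiculation, 0.2)  # digitization floor, below the cut
  expect_equal(disk$morphology, "Smooth")
  spik <- makePhantom(phantomSpec(noduleDiameterMm = 14, spacingMm = 1,
                                  spiculationLevel = 0.9, noiseSigma = 0,
                                  noduleClass = "malignant"))
  expect_gte(semanticFeatures(spik)$spiculation, 0.2)
  expect_true(semanticFeatures(spik)$morphology %in%
                c("Spiculated", "Irregular"))
})

test_that("the assembled feature vector is deterministic and ordered", {
  ds <- makeDataset(60, 0.5, imageSize = 64, noiseSigma = 0, seed = 21)
  fv <- extractFeatureVector(ds[[1]])
  expect_s3_class(fv, "FeatureVector")
  v1 <- featureVectorAsNumeric(fv)
  v2 <- featureVectorAsNumeric(extractFeatureVector(ds[[1]]))
  expect_identical(v1, v2)
  expect_equal(length(v1), length(featureSchema(5)))
  expect_named(v1, featureSchema(5))

  # malignant phantoms score lower circularity than benign ones
  fm <- featureMatrix(ds)
  lab <- vapply(ds, sampleLabel, "")
  expect_gte(sum(fm[lab == "malignant", "circularity"][1:30] <
                   fm[lab == "benign", "circularity"][1:30]), 27)
})
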