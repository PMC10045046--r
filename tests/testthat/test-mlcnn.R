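test_that("stratified splitting is deterministic and exact", {
  labels <- rep(c("benign", "malignant"), each = 5)
  sp <- splitDataset(labels, 0.8, seed = 1)
  expect_length(sp$train, 8); expect_length(sp$test, 2)
  expect_identical(sp$train, splitDataset(labels, 0.8, seed = 1)$train)

  labels2 <- rep(c("benign", "malignant"), each = 50)
  sp2 <- splitDataset(labels2, 0.8, seed = 3)
  expect_equal(sum(labels2[sp2$train] == "benign"), 40)
  expect_equal(sum(labels2[sp2$train] == "malignant"), 40)
  expect_equal(sum(labels2[sp2$test] == "benign"), 10)

  # disjoint cover on random label vectors
  set.seed(9)
  for (i in 1:20) {
    lab <- sample(c("benign", "malignant"), 20 + i, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (min(table(lab)) < 2) next
    s <- splitDataset(lab, 0.8, seed = i)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(lab))
  }
  expect_error(splitDataset(c("benign", "malignant", "benign")), "at least 5")
  expect_error(splitDataset(c(rep("benign", 9), "malignant")), "at least 2")
})

test_that("the network emits valid softmax probabilities deterministically", {
  cfg <- cnnConfig(inputSize = c(12, 12), nConvLayers = 2,
                   filtersPerLayer = c(3, 4), seed = 5)
  m <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m@params, m2@params)  # seeded initialization
  set.seed(2)
  for (i in 1:200) {
    p <- noduleCAD:::.cnnForward(m, array(rnorm(144), dim = c(12, 12, 1)))$probs
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    expect_length(p, 2)
  }
  # pooling depth that empties the grid is rejected
  expect_error(buildModel(cnnConfig(inputSize = c(8, 8), nConvLayers = 4)),
               "below 1x1")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- cnnConfig(inputSize = c(8, 8), nConvLayers = 1, filtersPerLayer = 2,
                   kernelSize = 3, poolSize = 2, sensorDim = 2, seed = 3)
  m <- buildModel(cfg)
  set.seed(7)
  x <- array(rnorm(64), dim = c(8, 8, 1)); sens <- rnorm(2); y <- 2L
  gr <- noduleCAD:::.cnnGradients(m, x, y, sens)
  numGrad <- function(set, get) {
    eps <- 1e-5
    mp <- m; mm <- m
    mp@params <- set(m@params, get(m@params) + eps)
    mm@params <- set(m@params, get(m@params) - eps)
    (noduleCAD:::.cnnGradients(mp, x, y, sens)$loss -
       noduleCAD:::.cnnGradients(mm, x, y, sens)$loss) / (2 * eps)
  }
  set.seed(8)
  checks <- list(
    function() { i <- sample(length(m@params$conv[[1]]$W), 1)
      c(gr$grads$conv[[1]]$W[i],
        numGrad(function(p, v) { p$conv[[1]]$W[i] <- v; p },
                function(p) p$conv[[1]]$W[i])) },
    function() { i <- sample(2, 1)
      c(gr$grads$conv[[1]]$b[i],
        numGrad(function(p, v) { p$conv[[1]]$b[i] <- v; p },
                function(p) p$conv[[1]]$b[i])) },
    function() { i <- sample(length(m@params$fc$W), 1)
      c(gr$grads$fc$W[i],
        numGrad(function(p, v) { p$fc$W[i] <- v; p },
                function(p) p$fc$W[i])) },
    function() { i <- sample(2, 1)
      c(gr$grads$fc$b[i],
        numGrad(function(p, v) { p$fc$b[i] <- v; p },
                function(p) p$fc$b[i])) })
  for (rep in 1:20) {
    got <- checks[[sample(4, 1)]]()
    expect_lt(abs(got[1] - got[2]) / max(abs(got[1]) + abs(got[2]), 1e-8),
              1e-4)
  }
})

test_that("training reduces the loss, is reproducible, and generalizes", {
  samples <- classifierCohort()
  split <- splitDataset(samples, 0.8, seed = 1)
  cfg <- cnnConfig(inputSize = c(32, 32), sensorDim = 5, seed = 1)
  m <- trainModel(buildModel(cfg), samples[split$train])
  lh <- lossHistory(m)
  expect_length(lh, 5)
  expect_lt(lh[5], lh[1])
  # determinism of the whole optimization
  mB <- trainModel(buildModel(cfg), samples[split$train])
  expect_identical(lossHistory(mB), lh)
  expect_identical(m@params, mB@params)
  # held-out accuracy on the 20% split
  pred <- predictCnn(m, samples[split$test])
  truth <- vapply(samples[split$test], sampleLabel, "")
  expect_gte(mean(pred$labels == truth), 0.9)
  expect_equal(rowSums(pred$probs), rep(1, length(truth)), tolerance = 1e-9)
})

test_that("a sensor-only model beats the majority baseline decisively", {
  samples <- classifierCohort()
  X <- t(vapply(samples, sensorValues, numeric(5)))
  y <- vapply(samples, sampleLabel, "")
  wins <- 0
  for (sd in 1:5) {
    sp <- splitDataset(y, 0.8, seed = sd)
    cfg <- cnnConfig(nConvLayers = 0, inputDim = 5, learningRate = 1e-2,
                     seed = sd)
    m <- trainModel(buildModel(cfg), X[sp$train, ], labels = y[sp$train])
    acc <- mean(predictCnn(m, X[sp$test, , drop = FALSE])$labels ==
                  y[sp$test])
    base <- max(table(y[sp$test])) / length(sp$test)
    if (acc >= base + 0.30) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("prediction reports entropy-based abstentions", {
  cfg <- cnnConfig(nConvLayers = 0, inputDim = 3, seed = 1,
                   entropyThreshold = 0.5)
  m <- buildModel(cfg)
  m@params$fc$W[] <- 0
  m@params$fc$b <- c(0, 0)           # exactly uniform output: 1 bit
  p <- predictCnn(m, matrix(rnorm(6), 2, 3))
  expect_equal(p$entropyBits, c(1, 1))
  expect_true(all(p$abstain))
  m@params$fc$b <- c(40, -40)        # fully confident: never abstains
  p2 <- predictCnn(m, matrix(rnorm(6), 2, 3))
  expect_false(any(p2$abstain))
  expect_true(all(p2$labels == "benign"))
})

test_that("class probability components are the empirical priors", {
  expect_equal(unname(classProbabilityComponents(c("A", "A", "B", "B"))),
               c(0.5, 0.5))
  expect_equal(unname(classProbabilityComponents(c("A", "A", "A", "B"))),
               c(0.75, 0.25))
  expect_equal(unname(classProbabilityComponents(rep("x", 4))), 1)
  expect_equal(sum(classProbabilityComponents(sample(letters[1:3], 50,
                                                     TRUE))), 1)
  expect_error(classProbabilityComponents(character(0)), "empty")
})
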