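# Compact multi-layer CNN classifier: (conv -> ReLU -> max-pool) blocks,
# fully connected softmax head, Adam training with batch size 1, manual
# backpropagation. No deep-learning framework is available in the target
# library, and the network is small enough that vectorized R (im2col
# convolutions as matrix products) trains it in seconds at desk scale.

#' Configuration of the compact CNN classifier
#'
#' Defaults follow the published training recipe: 3 convolution blocks,
#' ReLU activations, a softmax output, Adam optimization, 5 epochs and
#' batch size 1. The learning rate is the customary Adam default 1e-3
#' (not printed in the recipe).
#'
#' @param inputSize image side(s) in pixels, length 1 or 2 (images are
#'   resized bilinearly to this); ignored in "features"/"sensor" mode.
#' @param nConvLayers number of conv blocks (0 gives a softmax regression
#'   on a plain feature vector).
#' @param filtersPerLayer integer vector of filter counts, recycled to
#'   `nConvLayers`.
#' @param kernelSize square conv kernel side.
#' @param poolSize max-pool window (non-overlapping).
#' @param epochs training epochs (>= 1).
#' @param batchSize gradient accumulation size (>= 1; default 1).
#' @param learningRate Adam step size.
#' @param nClasses number of classes (>= 2).
#' @param classes class labels in output order.
#' @param sensorDim length of the sensor vector concatenated onto the
#'   flattened features entering the fully connected layer (0 = none).
#' @param inputDim input vector length for `nConvLayers = 0` models.
#' @param entropyThreshold optional abstention bound in bits for
#'   [predictCnn()].
#' @param seed RNG seed for initialization and epoch shuffling.
#' @return List of class `CnnConfig`.
#' @export
cnnConfig <- function(inputSize = c(64L, 64L), nConvLayers = 3L,
                      filtersPerLayer = c(4L, 8L, 8L), kernelSize = 3L,
                      poolSize = 2L, epochs = 5L, batchSize = 1L,
                      learningRate = 1e-3, nClasses = 2L,
                      classes = c("benign", "malignant"), sensorDim = 0L,
                      inputDim = NULL, entropyThreshold = NULL, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batchSize < 1) stop("batchSize must be >= 1")
  if (nClasses < 2) stop("nClasses must be >= 2")
  if (length(classes) != nClasses) stop("one label per class required")
  if (length(inputSize) == 1) inputSize <- rep(inputSize, 2)
  filtersPerLayer <- rep_len(filtersPerLayer, max(nConvLayers, 1L))
  structure(list(inputSize = as.integer(inputSize),
                 nConvLayers = as.integer(nConvLayers),
                 filtersPerLayer = as.integer(filtersPerLayer),
                 kernelSize = as.integer(kernelSize),
                 poolSize = as.integer(poolSize),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 nClasses = as.integer(nClasses), classes = classes,
                 sensorDim = as.integer(sensorDim),
                 inputDim = if (is.null(inputDim)) NULL
                            else as.integer(inputDim),
                 entropyThreshold = entropyThreshold,
                 seed = as.integer(seed)),
            class = "CnnConfig")
}

# im2col index matrix for an (H, W, C) input and k x k kernels.
.im2colIndex <- function(H, W, C, k) {
  outH <- H - k + 1L; outW <- W - k + 1L
  base <- as.vector(outer(seq_len(outH), (seq_len(outW) - 1L) * H, `+`))
  offs <- as.vector(outer(seq_len(k) - 1L,
                          as.vector(outer((seq_len(k) - 1L) * H,
                                          (seq_len(C) - 1L) * H * W, `+`)),
                          `+`))
  list(idx = outer(base, offs, `+`), outH = outH, outW = outW)
}

# Layer geometry for the whole stack; errors if pooling exhausts the grid.
.cnnGeometry <- function(config) {
  if (config$nConvLayers == 0L) {
    if (is.null(config$inputDim))
      stop("inputDim is required when nConvLayers = 0")
    return(list(layers = list(), flatLen = config$inputDim))
  }
  H <- config$inputSize[1]; W <- config$inputSize[2]; C <- 1L
  k <- config$kernelSize; p <- config$poolSize
  layers <- vector("list", config$nConvLayers)
  for (l in seq_len(config$nConvLayers)) {
    if (H < k || W < k) stop("input too small for convolution at layer ", l)
    ic <- .im2colIndex(H, W, C, k)
    pH <- ic$outH %/% p; pW <- ic$outW %/% p
    if (pH < 1 || pW < 1)
      stop("pooling reduces layer ", l, " below 1x1")
    layers[[l]] <- list(H = H, W = W, C = C, outH = ic$outH, outW = ic$outW,
                        pH = pH, pW = pW, idx = ic$idx,
                        nF = config$filtersPerLayer[l])
    H <- pH; W <- pW; C <- config$filtersPerLayer[l]
  }
  list(layers = layers, flatLen = H * W * C)
}

#' Build an untrained CNN
#'
#' Initializes convolution kernels with He-scaled Gaussian weights and the
#' softmax head with Xavier-scaled weights, deterministically under the
#' config seed.
#'
#' @param config a [cnnConfig()].
#' @return An untrained [CnnModel-class].
#' @export
buildModel <- function(config) {
  stopifnot(inherits(config, "CnnConfig"))
  geom <- .cnnGeometry(config)
  params <- withSeed(config$seed, {
    conv <- lapply(geom$layers, function(ly) {
      fanIn <- ncol(ly$idx)
      list(W = matrix(stats::rnorm(fanIn * ly$nF, 0, sqrt(2 / fanIn)),
                      fanIn, ly$nF),
           b = numeric(ly$nF))
    })
    inLen <- geom$flatLen + config$sensorDim
    list(conv = conv,
         fc = list(W = matrix(stats::rnorm(inLen * config$nClasses, 0,
                                           sqrt(1 / inLen)),
                              inLen, config$nClasses),
                   b = numeric(config$nClasses)))
  })
  m <- new("CnnModel", params = params, config = unclass(config),
           lossHistory = numeric(0), trained = FALSE)
  m@config$geom <- geom
  m
}

.softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# Forward pass; keepCache = TRUE retains per-layer activations for backprop.
.cnnForward <- function(model, x, sensor = numeric(0), keepCache = FALSE) {
  cfg <- model@config
  geom <- cfg$geom
  p <- cfg$poolSize
  cache <- list()
  if (cfg$nConvLayers == 0L) {
    flat <- as.numeric(x)
  } else {
    a <- x  # (H, W, 1) array
    for (l in seq_along(geom$layers)) {
      ly <- geom$layers[[l]]
      X <- matrix(a[ly$idx], nrow = nrow(ly$idx))
      Z <- X %*% model@params$conv[[l]]$W
      Z <- sweep(Z, 2, model@params$conv[[l]]$b, `+`)
      Zr <- array(Z, dim = c(ly$outH, ly$outW, ly$nF))
      A <- Zr * (Zr > 0)
      pooled <- array(-Inf, dim = c(ly$pH, ly$pW, ly$nF))
      argk <- array(1L, dim = dim(pooled))
      kk <- 0L
      for (dx in seq_len(p)) for (dy in seq_len(p)) {
        kk <- kk + 1L
        cand <- A[seq(dy, ly$pH * p, by = p), seq(dx, ly$pW * p, by = p), ,
                  drop = FALSE]
        upd <- cand > pooled
        pooled[upd] <- cand[upd]
        argk[upd] <- kk
      }
      if (keepCache)
        cache[[l]] <- list(X = X, Zr = Zr, argk = argk, input = a)
      a <- pooled
    }
    flat <- as.numeric(a)
  }
  v <- c(flat, sensor)
  scores <- drop(v %*% model@params$fc$W) + model@params$fc$b
  probs <- .softmax(scores)
  list(probs = probs, v = v, cache = cache)
}

# Loss and parameter gradients for one sample (y is the class index).
.cnnGradients <- function(model, x, y, sensor = numeric(0)) {
  cfg <- model@config
  geom <- cfg$geom
  p <- cfg$poolSize
  fw <- .cnnForward(model, x, sensor, keepCache = TRUE)
  probs <- fw$probs
  loss <- -log(max(probs[y], 1e-300))
  dscores <- probs
  dscores[y] <- dscores[y] - 1
  grads <- list(fc = list(W = outer(fw$v, dscores), b = dscores))
  dv <- drop(model@params$fc$W %*% dscores)
  if (cfg$nConvLayers > 0L) {
    flatLen <- geom$flatLen
    grads$conv <- vector("list", cfg$nConvLayers)
    lyLast <- geom$layers[[cfg$nConvLayers]]
    dpooled <- array(dv[seq_len(flatLen)],
                     dim = c(lyLast$pH, lyLast$pW, lyLast$nF))
    for (l in rev(seq_len(cfg$nConvLayers))) {
      ly <- geom$layers[[l]]
      ch <- fw$cache[[l]]
      dA <- array(0, dim = c(ly$outH, ly$outW, ly$nF))
      kk <- 0L
      for (dx in seq_len(p)) for (dy in seq_len(p)) {
        kk <- kk + 1L
        sel <- ch$argk == kk
        rows <- seq(dy, ly$pH * p, by = p)
        cols <- seq(dx, ly$pW * p, by = p)
        block <- dA[rows, cols, , drop = FALSE]
        block[sel] <- block[sel] + dpooled[sel]
        dA[rows, cols, ] <- block
      }
      dZ <- dA * (ch$Zr > 0)
      dZm <- matrix(dZ, nrow = ly$outH * ly$outW)
      grads$conv[[l]] <- list(W = crossprod(ch$X, dZm), b = colSums(dZm))
      if (l > 1L) {
        dXcol <- dZm %*% t(model@params$conv[[l]]$W)
        dxvec <- numeric(ly$H * ly$W * ly$C)
        gsum <- rowsum(as.vector(dXcol), group = as.vector(ly$idx))
        dxvec[as.integer(rownames(gsum))] <- gsum
        dpooled <- array(dxvec, dim = c(ly$H, ly$W, ly$C))
      }
    }
  }
  # order must mirror model@params for the recursive Adam walk
  grads <- grads[intersect(c("conv", "fc"), names(grads))]
  list(loss = loss, grads = grads, probs = probs)
}

# elementwise Adam update over a nested parameter/gradient structure
.adamInit <- function(params) rapply(params, function(p) p * 0, how = "replace")

.adamStep <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  walk(params, grads, state$m, state$v)
}

# Coerce assorted inputs into the model's tensors.
.prepareInputs <- function(samples, config) {
  if (is.list(samples) && length(samples) && is(samples[[1]], "NoduleSample")) {
    y <- match(vapply(samples, sampleLabel, ""), config$classes)
    if (anyNA(y)) stop("sample label outside the configured classes")
    sens <- if (config$sensorDim > 0)
      lapply(samples, function(s) sensorValues(s)[seq_len(config$sensorDim)])
    else rep(list(numeric(0)), length(samples))
    if (config$nConvLayers == 0L) {
      x <- lapply(samples, function(s)
        as.numeric(zscoreNormalize(resizeBilinear(
          sampleImage(s), config$inputSize[1], config$inputSize[2]))))
    } else {
      x <- lapply(samples, function(s)
        array(zscoreNormalize(resizeBilinear(
          sampleImage(s), config$inputSize[1], config$inputSize[2])),
          dim = c(config$inputSize, 1L)))
    }
    list(x = x, sensor = sens, y = y)
  } else if (is.matrix(samples)) {
    list(x = lapply(seq_len(nrow(samples)), function(i) samples[i, ]),
         sensor = rep(list(numeric(0)), nrow(samples)), y = NULL)
  } else stop("samples must be NoduleSample objects or a feature matrix")
}

#' Train a CNN with Adam on cross-entropy
#'
#' Runs `epochs` passes over the training samples in a seed-derived
#' shuffled order, accumulating gradients over `batchSize` samples per
#' Adam step (default 1), and records the mean cross-entropy per epoch.
#' Deterministic given the config seed and data order.
#'
#' @param model an untrained or trained [CnnModel-class].
#' @param samples list of [NoduleSample-class], or a numeric feature matrix
#'   (rows = samples) when `labels` is given.
#' @param labels optional label vector for matrix input.
#' @param epochs overrides the config epochs when given.
#' @return The trained model, with `lossHistory` filled.
#' @export
trainModel <- function(model, samples, labels = NULL, epochs = NULL) {
  stopifnot(is(model, "CnnModel"))
  cfg <- model@config
  prep <- .prepareInputs(samples, cfg)
  if (!is.null(labels))
    prep$y <- match(as.character(labels), cfg$classes)
  if (is.null(prep$y) || anyNA(prep$y))
    stop("labels are required and must match the configured classes")
  n <- length(prep$x)
  if (n == 0) stop("empty training set")
  nEpochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  params <- model@params
  state <- list(m = .adamInit(params), v = .adamInit(params))
  t <- 0L
  lossHist <- numeric(nEpochs)
  withSeed(deriveSeed(cfg$seed, 977L), {
    for (ep in seq_len(nEpochs)) {
      ord <- sample.int(n)
      losses <- numeric(length(ord))
      bi <- 0L
      accum <- NULL
      mTmp <- model
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        mTmp@params <- params
        gr <- .cnnGradients(mTmp, prep$x[[i]], prep$y[i], prep$sensor[[i]])
        if (!is.finite(gr$loss))
          stop("non-finite loss at epoch ", ep, ", sample ", i,
               " (probs: ", paste(signif(gr$probs, 3), collapse = ", "), ")")
        losses[ii] <- gr$loss
        accum <- if (is.null(accum)) gr$grads
                 else .sumGrads(accum, gr$grads)
        bi <- bi + 1L
        if (bi == cfg$batchSize || ii == length(ord)) {
          sc <- .scaleGrads(accum, 1 / bi)
          t <- t + 1L
          upd <- .adamStep(params, sc, state, cfg$learningRate, t)
          params <- upd$p
          state <- list(m = upd$m, v = upd$v)
          accum <- NULL
          bi <- 0L
        }
      }
      lossHist[ep] <- mean(losses)
    }
  })
  model@params <- params
  model@lossHistory <- c(model@lossHistory, lossHist)
  model@trained <- TRUE
  model
}

.sumGrads <- function(a, b) {
  if (is.list(a)) Map(.sumGrads, a, b) else a + b
}
.scaleGrads <- function(a, s) {
  if (is.list(a)) lapply(a, .scaleGrads, s = s) else a * s
}

#' Predict class probabilities and labels
#'
#' Applies the trained network; the hard label is the argmax class. When
#' an entropy threshold (bits) is configured or supplied, predictions
#' whose probability-distribution entropy exceeds the bound are flagged
#' as abstentions (the label is still reported).
#'
#' @param model a trained [CnnModel-class].
#' @param samples list of [NoduleSample-class] or feature matrix.
#' @param entropyThreshold optional override of the config bound.
#' @return List: `probs` (n x nClasses matrix), `labels`, `entropyBits`,
#'   `abstain`.
#' @export
predictCnn <- function(model, samples, entropyThreshold = NULL) {
  stopifnot(is(model, "CnnModel"))
  cfg <- model@config
  prep <- .prepareInputs(samples, cfg)
  probs <- t(vapply(seq_along(prep$x), function(i)
    .cnnForward(model, prep$x[[i]], prep$sensor[[i]])$probs,
    numeric(cfg$nClasses)))
  colnames(probs) <- cfg$classes
  ent <- apply(probs, 1, function(p) {
    p <- p[p > 0]; -sum(p * log2(p))
  })
  thr <- entropyThreshold %||% cfg$entropyThreshold
  list(probs = probs,
       labels = cfg$classes[max.col(probs, ties.method = "first")],
       entropyBits = ent,
       abstain = if (is.null(thr)) rep(FALSE, nrow(probs)) else ent > thr)
}

#' @describeIn predictCnn S4 `predict` method for CnnModel.
#' @param object a [CnnModel-class].
#' @param ... passed to [predictCnn()].
#' @export
setMethod("predict", "CnnModel", function(object, ...) predictCnn(object, ...))

#' Stratified train/test split
#'
#' Splits sample indices 80/20 (by default) stratified by class:
#' `round(fraction * n_c)` training samples per class, drawn
#' deterministically under the seed.
#'
#' @param samples list of [NoduleSample-class] or a label vector.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return List of class `DatasetSplit` with `train`, `test`, `fraction`,
#'   `seed`.
#' @export
splitDataset <- function(samples, fraction = 0.8, seed = 1L) {
  labels <- if (is.list(samples)) vapply(samples, sampleLabel, "")
            else as.character(samples)
  n <- length(labels)
  if (n < 5) stop("need at least 5 samples to split")
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 samples")
  train <- integer(0)
  withSeed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      nTrain <- round(fraction * length(idx))
      nTrain <- min(max(nTrain, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, nTrain))
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "DatasetSplit")
}

#' Per-class probability components
#'
#' The empirical class prior `Pcomp(i) = count_i / count_total`, the
#' diagnostic the classification pseudocode accumulates.
#'
#' @param labels nonempty label vector.
#' @return Named numeric vector summing to 1.
#' @export
classProbabilityComponents <- function(labels) {
  if (!length(labels)) stop("empty labels")
  tab <- table(labels)
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, names(tab))
}
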