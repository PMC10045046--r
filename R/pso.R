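# Particle swarm optimization over box-bounded hyperparameter spaces.

#' Define a box-bounded hyperparameter search space
#'
#' Each dimension has a lower and upper bound and a type: "continuous"
#' dimensions pass through unchanged, "integer" dimensions are kept
#' continuous during the search and rounded at objective-evaluation time,
#' and "log" dimensions are searched on a log10 scale (bounds given on the
#' natural scale, e.g. learning rates).
#'
#' @param lower,upper numeric bounds, `lower < upper` per dimension.
#' @param type character vector: "continuous", "integer" or "log".
#' @param names optional dimension names.
#' @return List of class `SearchSpace`.
#' @export
searchSpace <- function(lower, upper, type = rep("continuous", length(lower)),
                        names = NULL) {
  if (length(lower) != length(upper)) stop("bound lengths differ")
  if (any(!type %in% c("continuous", "integer", "log")))
    stop("unknown dimension type")
  lo <- ifelse(type == "log", log10(lower), lower)
  hi <- ifelse(type == "log", log10(upper), upper)
  if (any(lo >= hi)) stop("each dimension needs lower < upper")
  structure(list(lower = lo, upper = hi, type = type,
                 names = names %||% paste0("dim", seq_along(lo))),
            class = "SearchSpace")
}

#' Decode a raw particle position into hyperparameter values
#'
#' @param space a [searchSpace()].
#' @param position raw position vector.
#' @return Named numeric vector on the natural scale (integers rounded).
#' @export
decodePosition <- function(space, position) {
  out <- position
  out[space$type == "log"] <- 10^out[space$type == "log"]
  out[space$type == "integer"] <- round(out[space$type == "integer"])
  stats::setNames(out, space$names)
}

#' PSO fitness: one minus the root-mean-square prediction error
#'
#' `fitness = 1 - sqrt(mean((Y - Yhat)^2))` over one-hot targets and
#' predicted class probabilities (or hard one-hot predictions). Perfect
#' predictions give 1; fully inverted one-hot predictions give 0. A
#' `1 - MSE` variant is available.
#'
#' @param truth factor/character labels, or an n x C one-hot (or
#'   probability) matrix.
#' @param predicted n x C probability matrix, or labels.
#' @param classes class levels used to one-hot encode label input.
#' @param variant "rmse" (default) or "mse".
#' @return Scalar fitness <= 1.
#' @export
psoFitness <- function(truth, predicted, classes = NULL,
                       variant = c("rmse", "mse")) {
  variant <- match.arg(variant)
  oneHot <- function(z, classes) {
    z <- as.character(z)
    if (is.null(classes)) classes <- sort(unique(z))
    m <- matrix(0, length(z), length(classes))
    m[cbind(seq_along(z), match(z, classes))] <- 1
    m
  }
  if (!is.matrix(truth)) {
    classes <- classes %||% sort(unique(c(as.character(truth),
      if (!is.matrix(predicted)) as.character(predicted))))
    truth <- oneHot(truth, classes)
  }
  if (!is.matrix(predicted)) predicted <- oneHot(predicted, classes)
  if (!all(dim(truth) == dim(predicted))) stop("dimension mismatch")
  if (!length(truth)) stop("empty input")
  mse <- mean((truth - predicted)^2)
  if (variant == "rmse") 1 - sqrt(mse) else 1 - mse
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly within the bounds, velocities start at
#' zero, and every particle is evaluated once to seed the personal and
#' global bests.
#'
#' @param space a [searchSpace()].
#' @param objective function taking a decoded position, returning a
#'   fitness to maximize.
#' @param nParticles swarm size (default 10).
#' @param seed RNG seed.
#' @param w,c1,c2 inertia weight and cognitive/social constants
#'   (defaults 0.85, 2, 2).
#' @return A [SwarmState-class].
#' @export
initSwarm <- function(space, objective, nParticles = 10L, seed = 1L,
                      w = 0.85, c1 = 2, c2 = 2) {
  stopifnot(inherits(space, "SearchSpace"))
  d <- length(space$lower)
  pos <- withSeed(seed, {
    matrix(stats::runif(nParticles * d, rep(space$lower, each = nParticles),
                        rep(space$upper, each = nParticles)),
           nParticles, d)
  })
  fit <- apply(pos, 1, function(p) objective(decodePosition(space, p)))
  fit[!is.finite(fit)] <- -Inf
  gi <- which.max(fit)
  new("SwarmState", positions = pos, velocities = matrix(0, nParticles, d),
      pbestPositions = pos, pbestFitness = fit,
      gbestPosition = pos[gi, ], gbestFitness = fit[gi],
      iteration = 0L, w = w, c1 = c1, c2 = c2, space = unclass(space))
}

#' One PSO iteration
#'
#' For every particle the velocity is updated with the inertia-weighted
#' rule `V <- w V + c1 r1 (pbest - p) + c2 r2 (gbest - p)` (r1, r2 drawn
#' per dimension per particle), clamped to half the dimension range; the
#' position moves by the velocity and is clamped to the bounds; the
#' objective is evaluated and personal/global bests updated (a non-finite
#' objective value skips the best-update with a warning). The global best
#' is non-decreasing.
#'
#' @param swarm a [SwarmState-class].
#' @param objective fitness function over decoded positions (maximized).
#' @return The advanced [SwarmState-class].
#' @export
psoStep <- function(swarm, objective) {
  stopifnot(is(swarm, "SwarmState"))
  sp <- swarm@space
  n <- nrow(swarm@positions); d <- ncol(swarm@positions)
  vmax <- (sp$upper - sp$lower) / 2
  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  loM <- matrix(sp$lower, n, d, byrow = TRUE)
  hiM <- matrix(sp$upper, n, d, byrow = TRUE)
  vmaxM <- matrix(vmax, n, d, byrow = TRUE)
  gbM <- matrix(swarm@gbestPosition, n, d, byrow = TRUE)
  V <- swarm@w * swarm@velocities +
    swarm@c1 * r1 * (swarm@pbestPositions - swarm@positions) +
    swarm@c2 * r2 * (gbM - swarm@positions)
  V <- pmin(pmax(V, -vmaxM), vmaxM)
  P <- pmin(pmax(swarm@positions + V, loM), hiM)
  fit <- apply(P, 1, function(p) objective(decodePosition(
    structure(sp, class = "SearchSpace"), p)))
  bad <- !is.finite(fit)
  if (any(bad)) {
    warning(sum(bad), " particle(s) returned a non-finite objective; skipped")
    fit[bad] <- -Inf
  }
  improved <- fit > swarm@pbestFitness
  swarm@pbestPositions[improved, ] <- P[improved, ]
  swarm@pbestFitness[improved] <- fit[improved]
  gi <- which.max(swarm@pbestFitness)
  swarm@gbestPosition <- swarm@pbestPositions[gi, ]
  swarm@gbestFitness <- swarm@pbestFitness[gi]
  swarm@positions <- P
  swarm@velocities <- V
  swarm@iteration <- swarm@iteration + 1L
  swarm
}

#' Run PSO over a search space
#'
#' @param space a [searchSpace()].
#' @param objective fitness function over decoded positions (maximized).
#' @param nParticles swarm size (default 10).
#' @param nIterations iterations after initialization (default 10).
#' @param seed RNG seed (initialization and the r1/r2 draws).
#' @param w,c1,c2 PSO constants.
#' @return List: `bestPosition` (decoded), `bestFitness`, `trace`
#'   (data.frame of iteration and gbest fitness), `swarm`.
#' @export
psoOptimize <- function(space, objective, nParticles = 10L,
                        nIterations = 10L, seed = 1L,
                        w = 0.85, c1 = 2, c2 = 2) {
  swarm <- initSwarm(space, objective, nParticles, seed, w, c1, c2)
  trace <- data.frame(iteration = 0L, gbestFitness = swarm@gbestFitness)
  withSeed(deriveSeed(seed, 131L), {
    for (it in seq_len(nIterations)) {
      swarm <- psoStep(swarm, objective)
      trace <- rbind(trace, data.frame(iteration = it,
                                       gbestFitness = swarm@gbestFitness))
    }
  })
  list(bestPosition = decodePosition(structure(swarm@space,
                                               class = "SearchSpace"),
                                     swarm@gbestPosition),
       bestFitness = swarm@gbestFitness, trace = trace, swarm = swarm)
}

#' Tune CNN hyperparameters with PSO
#'
#' Splits the samples into a training and validation part, then searches
#' the given space (by default: filters of the first block, learning rate
#' on a log scale, and batch size) with [psoOptimize()]; the objective
#' trains a CNN with the candidate hyperparameters for `searchEpochs`
#' epochs and returns the validation [psoFitness()]. The best
#' configuration is refit at the full epoch count.
#'
#' @param samples list of [NoduleSample-class].
#' @param space a [searchSpace()] whose names match [cnnConfig()] argument
#'   names (integer-typed where appropriate); defaults to
#'   filters/learning-rate/batch-size.
#' @param baseConfig a [cnnConfig()] providing all non-searched settings.
#' @param nParticles,nIterations,seed PSO settings (defaults 10, 10).
#' @param searchEpochs reduced epochs used inside the search (default 2).
#' @return List: `bestConfig`, `bestFitness`, `trace`, `model` (the
#'   refit model), `split`.
#' @export
optimizeHyperparameters <- function(samples, space = NULL,
                                    baseConfig = cnnConfig(),
                                    nParticles = 10L, nIterations = 10L,
                                    seed = 1L, searchEpochs = 2L) {
  if (is.null(space))
    space <- searchSpace(lower = c(filters = 2, learningRate = 1e-4,
                                   batchSize = 1),
                         upper = c(filters = 12, learningRate = 5e-2,
                                   batchSize = 4),
                         type = c("integer", "log", "integer"),
                         names = c("filters", "learningRate", "batchSize"))
  split <- splitDataset(samples, 0.8, seed = deriveSeed(seed, 7L))
  trainSet <- samples[split$train]
  valSet <- samples[split$test]
  valLabels <- vapply(valSet, sampleLabel, "")
  makeCfg <- function(hp) {
    cfg <- baseConfig
    if ("filters" %in% names(hp))
      cfg$filtersPerLayer <- rep(as.integer(hp[["filters"]]),
                                 max(cfg$nConvLayers, 1L))
    if ("learningRate" %in% names(hp)) cfg$learningRate <- hp[["learningRate"]]
    if ("batchSize" %in% names(hp))
      cfg$batchSize <- as.integer(hp[["batchSize"]])
    class(cfg) <- "CnnConfig"
    cfg
  }
  objective <- function(hp) {
    cfg <- makeCfg(hp)
    model <- trainModel(buildModel(cfg), trainSet, epochs = searchEpochs)
    pred <- predictCnn(model, valSet)
    psoFitness(valLabels, pred$probs, classes = cfg$classes)
  }
  res <- psoOptimize(space, objective, nParticles, nIterations, seed)
  bestCfg <- makeCfg(res$bestPosition)
  model <- trainModel(buildModel(bestCfg), trainSet)
  list(bestConfig = bestCfg, bestFitness = res$bestFitness,
       trace = res$trace, model = model, split = split)
}
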