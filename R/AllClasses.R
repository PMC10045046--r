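#' @import methods
NULL

#' CtVolume: a grayscale CT intensity grid with voxel spacing
#'
#' Container for a 2-D slice or 3-D volume of CT-like intensities together
#' with the isotropic voxel spacing in millimetres. This is the unit the
#' denoiser and the feature extractor consume.
#'
#' @slot voxels numeric matrix (2-D) or 3-D array of intensities.
#' @slot spacingMm positive numeric scalar, mm per voxel edge.
#'
#' @seealso [ctVolume()], [denoiseVolume()], [waveletDecompose()]
#' @exportClass CtVolume
setClass("CtVolume",
  representation(voxels = "array", spacingMm = "numeric"),
  validity = function(object) {
    nd <- length(dim(object@voxels))
    if (!nd %in% c(2L, 3L))
      return("voxels must be a 2-D matrix or 3-D array")
    if (!all(is.finite(object@voxels)))
      return("voxels must be finite")
    if (length(object@spacingMm) != 1L || !is.finite(object@spacingMm) ||
        object@spacingMm <= 0)
      return("spacingMm must be a positive scalar")
    TRUE
  })

#' Construct a CtVolume
#'
#' @param voxels numeric matrix or 3-D array of intensities.
#' @param spacingMm voxel spacing in mm (default 1).
#' @return A [CtVolume-class] object.
#' @examples
#' vol <- ctVolume(array(rnorm(8^3), dim = c(8, 8, 8)))
#' dim(voxels(vol))
#' @export
ctVolume <- function(voxels, spacingMm = 1) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = dim(voxels))
  new("CtVolume", voxels = voxels, spacingMm = as.numeric(spacingMm))
}

#' SubbandSet: one-level wavelet subbands of a volume
#'
#' The result of a one-level separable orthogonal wavelet transform:
#' 4 subbands (LL, LH, HL, HH) for 2-D input, 8 subbands (LLL ... HHH) for
#' 3-D input. Letters are ordered by array dimension; "H" marks the
#' high-pass branch. The finest diagonal subband (HH / HHH) carries the
#' noise-level estimate.
#'
#' @slot subbands named list of coefficient arrays.
#' @slot waveletName character, filter identifier ("haar" or "d8").
#' @slot originalShape integer vector, the pre-padding input dimensions.
#'
#' @seealso [waveletDecompose()], [waveletReconstruct()], [estimateThreshold()]
#' @exportClass SubbandSet
setClass("SubbandSet",
  representation(subbands = "list", waveletName = "character",
                 originalShape = "integer"),
  validity = function(object) {
    nms <- names(object@subbands)
    want2 <- c("LL", "LH", "HL", "HH")
    want3 <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
    if (!(identical(sort(nms), sort(want2)) ||
          identical(sort(nms), sort(want3))))
      return("subbands must be named LL..HH (2-D) or LLL..HHH (3-D)")
    dims <- unique(lapply(object@subbands, dim))
    if (length(dims) != 1L)
      return("all subbands must share one shape")
    TRUE
  })

#' ThresholdEstimate: BayesShrink quantities for one subband
#'
#' Holds the noise standard deviation, the observed and signal standard
#' deviations, the Bayesian threshold T_B = sigma_N^2 / sigma_s, the beta
#' fed to the curve-fitted modifier and the modifier value gamma.
#' When the signal deviation collapses to zero, T_B is the documented
#' shrink-all sentinel (the subband's maximum absolute coefficient).
#'
#' @slot sigmaN noise standard deviation (>= 0).
#' @slot sigmaY observed subband root-mean-square.
#' @slot sigmaS estimated signal standard deviation (>= 0).
#' @slot tB Bayesian threshold (>= 0).
#' @slot beta standard deviation fed to the modifier.
#' @slot gamma curve-fitted threshold modifier.
#' @slot sentinel logical, TRUE when tB is the shrink-all sentinel.
#'
#' @seealso [estimateThreshold()], [gammaModifier()]
#' @exportClass ThresholdEstimate
setClass("ThresholdEstimate",
  representation(sigmaN = "numeric", sigmaY = "numeric", sigmaS = "numeric",
                 tB = "numeric", beta = "numeric", gamma = "numeric",
                 sentinel = "logical"),
  validity = function(object) {
    if (object@sigmaN < 0) return("sigmaN must be >= 0")
    if (object@sigmaS < 0) return("sigmaS must be >= 0")
    if (object@tB < 0) return("tB must be >= 0")
    TRUE
  })

#' NoduleSample: an image patch with mask, label and optional sensor record
#'
#' The atom of training and testing: a grayscale patch, a binary nodule
#' mask on the same grid, a class label (benign or malignant), the pixel
#' spacing, optional fixed-length sensor features, and free-form metadata
#' (e.g. the upper-lobe flag used by the semantic features).
#'
#' @slot image numeric matrix of intensities.
#' @slot mask logical matrix, same shape, at least one TRUE pixel.
#' @slot label character, "benign" or "malignant".
#' @slot spacingMm positive scalar, mm per pixel.
#' @slot sensor numeric vector of sensor features (length 0 when absent).
#' @slot meta list of optional metadata.
#'
#' @seealso [makePhantom()], [makeDataset()], [extractFeatureVector()]
#' @exportClass NoduleSample
setClass("NoduleSample",
  representation(image = "matrix", mask = "matrix", label = "character",
                 spacingMm = "numeric", sensor = "numeric", meta = "list"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@mask)))
      return("image and mask must share one shape")
    if (!is.logical(object@mask))
      return("mask must be logical")
    if (!any(object@mask))
      return("mask must be nonempty")
    if (!object@label %in% c("benign", "malignant"))
      return("label must be 'benign' or 'malignant'")
    if (length(object@spacingMm) != 1L || object@spacingMm <= 0)
      return("spacingMm must be a positive scalar")
    if (length(object@sensor) && !all(is.finite(object@sensor)))
      return("sensor values must be finite")
    TRUE
  })

#' SwarmState: particle swarm optimizer state
#'
#' Positions, velocities and personal bests of all particles plus the
#' swarm's global best over a box-bounded hyperparameter search space.
#' The PSO constants default to the inertia weight w = 0.85 and cognitive /
#' social constants c1 = c2 = 2.
#'
#' @slot positions nParticles x nDims numeric matrix.
#' @slot velocities nParticles x nDims numeric matrix.
#' @slot pbestPositions nParticles x nDims numeric matrix.
#' @slot pbestFitness numeric vector, best fitness seen per particle.
#' @slot gbestPosition numeric vector.
#' @slot gbestFitness numeric scalar.
#' @slot iteration integer counter.
#' @slot w,c1,c2 PSO constants.
#' @slot space list describing the search space (see [searchSpace()]).
#'
#' @seealso [initSwarm()], [psoStep()], [psoOptimize()]
#' @exportClass SwarmState
setClass("SwarmState",
  representation(positions = "matrix", velocities = "matrix",
                 pbestPositions = "matrix", pbestFitness = "numeric",
                 gbestPosition = "numeric", gbestFitness = "numeric",
                 iteration = "integer", w = "numeric", c1 = "numeric",
                 c2 = "numeric", space = "list"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (!identical(dim(object@positions), dim(object@velocities)))
      return("positions and velocities must share one shape")
    if (length(object@pbestFitness) != n)
      return("one pbest fitness per particle required")
    if (length(object@gbestFitness) == 1L && is.finite(object@gbestFitness) &&
        length(object@pbestFitness) &&
        object@gbestFitness < max(object@pbestFitness) - 1e-9)
      return("gbestFitness must be the max over pbestFitness")
    TRUE
  })

#' CnnModel: a compact convolutional network classifier
#'
#' A stack of (convolution, ReLU, max-pool) blocks followed by a fully
#' connected softmax layer. Optional sensor features are concatenated onto
#' the flattened activations entering the fully connected layer. With zero
#' convolution blocks the model degrades to a softmax regression on a plain
#' feature vector, which serves the feature-only and sensor-only paths.
#'
#' @slot params list of parameter arrays per layer.
#' @slot config list, the [cnnConfig()] used to build the model.
#' @slot lossHistory numeric vector, mean cross-entropy per trained epoch.
#' @slot trained logical.
#'
#' @seealso [buildModel()], [trainModel()], [predictCnn()]
#' @exportClass CnnModel
setClass("CnnModel",
  representation(params = "list", config = "list",
                 lossHistory = "numeric", trained = "logical"))

## ---- accessors ----

#' @describeIn CtVolume-class extract the voxel array.
#' @param object a CtVolume.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname CtVolume-class
#' @export
setMethod("voxels", "CtVolume", function(object) object@voxels)

#' Voxel or pixel spacing in millimetres
#' @param object a CtVolume or NoduleSample.
#' @export
setGeneric("spacingMm", function(object) standardGeneric("spacingMm"))
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "CtVolume", function(object) object@spacingMm)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "NoduleSample", function(object) object@spacingMm)

#' Subband list of a SubbandSet
#' @param object a SubbandSet.
#' @export
setGeneric("subbands", function(object) standardGeneric("subbands"))
#' @rdname subbands
#' @export
setMethod("subbands", "SubbandSet", function(object) object@subbands)

#' @describeIn NoduleSample-class the image matrix.
#' @param object a NoduleSample.
#' @export
setGeneric("sampleImage", function(object) standardGeneric("sampleImage"))
#' @rdname NoduleSample-class
#' @export
setMethod("sampleImage", "NoduleSample", function(object) object@image)

#' @describeIn NoduleSample-class the binary mask.
#' @export
setGeneric("sampleMask", function(object) standardGeneric("sampleMask"))
#' @rdname NoduleSample-class
#' @export
setMethod("sampleMask", "NoduleSample", function(object) object@mask)

#' @describeIn NoduleSample-class the class label.
#' @export
setGeneric("sampleLabel", function(object) standardGeneric("sampleLabel"))
#' @rdname NoduleSample-class
#' @export
setMethod("sampleLabel", "NoduleSample", function(object) object@label)

#' @describeIn NoduleSample-class the sensor feature vector (may be empty).
#' @export
setGeneric("sensorValues", function(object) standardGeneric("sensorValues"))
#' @rdname NoduleSample-class
#' @export
setMethod("sensorValues", "NoduleSample", function(object) object@sensor)

#' Global best position and fitness of a swarm
#' @param object a SwarmState.
#' @export
setGeneric("gbest", function(object) standardGeneric("gbest"))
#' @rdname gbest
#' @export
setMethod("gbest", "SwarmState", function(object)
  list(position = object@gbestPosition, fitness = object@gbestFitness))

#' Per-epoch training loss of a CnnModel
#' @param object a CnnModel.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
#' @rdname lossHistory
#' @export
setMethod("lossHistory", "CnnModel", function(object) object@lossHistory)

## ---- show methods ----

setMethod("show", "CtVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CtVolume: %s voxels, spacing %.3g mm, range [%.3g, %.3g]\n",
              paste(d, collapse = " x "), object@spacingMm,
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "SubbandSet", function(object) {
  d <- dim(object@subbands[[1L]])
  cat(sprintf("SubbandSet: %d subbands of %s ('%s' wavelet, input %s)\n",
              length(object@subbands), paste(d, collapse = " x "),
              object@waveletName,
              paste(object@originalShape, collapse = " x ")))
})

setMethod("show", "ThresholdEstimate", function(object) {
  cat(sprintf(
    "ThresholdEstimate: sigmaN %.4g, sigmaY %.4g, sigmaS %.4g, T_B %.4g%s, gamma %.4g\n",
    object@sigmaN, object@sigmaY, object@sigmaS, object@tB,
    if (object@sentinel) " (sentinel)" else "", object@gamma))
})

setMethod("show", "NoduleSample", function(object) {
  cat(sprintf(
    "NoduleSample: %s px, %s, spacing %.3g mm, %d mask px, %d sensor values\n",
    paste(dim(object@image), collapse = " x "), object@label,
    object@spacingMm, sum(object@mask), length(object@sensor)))
})

setMethod("show", "SwarmState", function(object) {
  cat(sprintf(
    "SwarmState: %d particles, %d dims, iteration %d, gbest fitness %.6g\n",
    nrow(object@positions), ncol(object@positions), object@iteration,
    object@gbestFitness))
})

setMethod("show", "CnnModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CnnModel: %d conv blocks, input %s, %d classes, %s (epochs trained: %d)\n",
    cfg$nConvLayers, paste(cfg$inputSize, collapse = "x"), cfg$nClasses,
    if (object@trained) "trained" else "untrained",
    length(object@lossHistory)))
})
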