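#' Specification for one synthetic nodule phantom
#'
#' Describes a CT-like grayscale slice containing one elliptical nodule,
#' optionally with radial spikes emulating spiculation. Identical specs
#' (including the seed) yield bit-identical phantoms.
#'
#' Defaults state the simulated world once: 64 px slices at 0.7 mm/px (the
#' middle of the 0.418--1 mm slice-size range typical of public lung CT
#' sign databases), a 10 mm nodule, lung-field background level 60 with a
#' nodule contrast of 45 on an 8-bit-like intensity scale, and additive
#' Gaussian noise of standard deviation 15 (contrast = 3 sigma).
#'
#' @param imageSize pixels per side of the square slice (>= 16).
#' @param spacingMm mm per pixel.
#' @param noduleDiameterMm equivalent-circle diameter of the nodule in mm.
#' @param noduleClass "benign" or "malignant".
#' @param spiculationLevel spike strength in [0, 1]; 0 gives a smooth
#'   ellipse. Malignant phantoms are the ones drawn with high levels.
#' @param contrast intensity offset of the nodule over the background.
#' @param noiseSigma standard deviation of additive Gaussian noise (>= 0).
#' @param background constant lung-field intensity level.
#' @param gradientAmp amplitude of an optional low-frequency background
#'   gradient (0 disables it).
#' @param seed integer RNG seed.
#' @return A validated list of class `PhantomSpec`.
#' @seealso [makePhantom()], [makeDataset()]
#' @export
phantomSpec <- function(imageSize = 64, spacingMm = 0.7,
                        noduleDiameterMm = 10,
                        noduleClass = c("benign", "malignant"),
                        spiculationLevel = 0, contrast = 45,
                        noiseSigma = 15, background = 60,
                        gradientAmp = 0, seed = 1L) {
  noduleClass <- match.arg(noduleClass)
  if (imageSize < 16) stop("imageSize must be >= 16")
  if (noduleDiameterMm <= 0) stop("noduleDiameterMm must be > 0")
  if (spiculationLevel < 0 || spiculationLevel > 1)
    stop("spiculationLevel must lie in [0, 1]")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  structure(list(imageSize = as.integer(imageSize),
                 spacingMm = spacingMm,
                 noduleDiameterMm = noduleDiameterMm,
                 noduleClass = noduleClass,
                 spiculationLevel = spiculationLevel,
                 contrast = contrast, noiseSigma = noiseSigma,
                 background = background, gradientAmp = gradientAmp,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Relative amplitude of the sinusoidal radial spikes at spiculationLevel 1.
.spikeAmp <- 0.35

#' Render one synthetic nodule phantom
#'
#' Draws a centred nodule as a base ellipse (axis ratio sampled uniformly in
#' [1, 1.4], random orientation) whose equivalent-circle diameter equals the
#' requested diameter, perturbed by a sinusoidal radial spike pattern with
#' amplitude proportional to `spiculationLevel` (6--12 spikes). The image is
#' background + optional low-frequency gradient + contrast times an
#' anti-aliased nodule coverage map, plus additive Gaussian noise; the mask
#' marks pixels with coverage >= 0.5. Fully deterministic under the spec's
#' seed.
#'
#' @param spec a [phantomSpec()].
#' @return A [NoduleSample-class] (no sensor record; attach one via
#'   [makeDataset()]).
#' @examples
#' s <- makePhantom(phantomSpec(noduleDiameterMm = 10, spacingMm = 1,
#'                              noiseSigma = 0))
#' sum(sampleMask(s))  # ~ pi * 5^2 pixels
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  n <- spec$imageSize
  r0 <- spec$noduleDiameterMm / spec$spacingMm / 2  # px
  sp <- spec$spiculationLevel
  if (r0 * sqrt(1.4) * (1 + .spikeAmp * sp) >= n / 2)
    stop("nodule diameter exceeds the image extent")
  withSeed(spec$seed, {
    ratio <- stats::runif(1, 1, 1.4)
    phi <- stats::runif(1, 0, 2 * pi)
    nSpikes <- sample(6:12, 1)
    spikePhase <- stats::runif(1, 0, 2 * pi)
    a <- r0 * sqrt(ratio)
    b <- r0 / sqrt(ratio)
    ctr <- (n + 1) / 2
    dx <- matrix(seq_len(n) - ctr, n, n)            # rows
    dy <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)  # cols
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    tr <- theta - phi
    rEll <- a * b / sqrt((b * cos(tr))^2 + (a * sin(tr))^2)
    rNod <- rEll * (1 + .spikeAmp * sp * sin(nSpikes * theta + spikePhase))
    coverage <- clamp01(rNod - rho + 0.5)           # anti-aliased edge
    img <- spec$background + spec$contrast * coverage
    if (spec$gradientAmp != 0) {
      gdir <- stats::runif(1, 0, 2 * pi)
      img <- img + spec$gradientAmp *
        ((dx * cos(gdir) + dy * sin(gdir)) / n)
    }
    if (spec$noiseSigma > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noiseSigma), n, n)
    mask <- coverage >= 0.5
    new("NoduleSample", image = img, mask = mask, label = spec$noduleClass,
        spacingMm = spec$spacingMm, sensor = numeric(0),
        meta = list(spec = spec, upperLobe = NA))
  })
}

#' Add i.i.d. Gaussian noise to an image
#'
#' @param image numeric matrix or array.
#' @param noiseSigma noise standard deviation (>= 0; 0 returns the input
#'   unchanged).
#' @param seed integer seed making the residual reproducible.
#' @return The noisy image, same shape.
#' @export
addNoise <- function(image, noiseSigma, seed = 1L) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (noiseSigma == 0) return(image)
  withSeed(seed, image + array(stats::rnorm(length(image), 0, noiseSigma),
                               dim = dim(image) %||% length(image)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a reproducible phantom dataset with sensor records
#'
#' Produces `n` [NoduleSample-class] phantoms, `round(n * classBalance)` of
#' them malignant (listed first), each with a per-sample seed derived from
#' the master seed by a counter-based rule so the dataset is extensible
#' without reshuffling earlier samples. Benign nodules draw low spiculation
#' levels and malignant ones high levels, reproducing the morphology axis
#' (smooth versus spiculated) that separates the classes. Each sample also
#' carries a class-conditional Gaussian sensor record: benign dimensions are
#' N(0, sensorSigma^2) and malignant ones N(sensorShift, sensorSigma^2).
#'
#' @param n number of samples (>= 2).
#' @param classBalance malignant fraction, strictly between 0 and 1 and such
#'   that both classes are nonempty.
#' @param imageSize,spacingMm,contrast,noiseSigma,background,gradientAmp
#'   passed to [phantomSpec()].
#' @param diameterRangeMm nodule diameters are drawn uniformly in this range.
#' @param benignSpiculation,malignantSpiculation per-class uniform ranges
#'   for the spiculation level.
#' @param sensorDim length of the sensor record (0 disables sensors).
#' @param sensorShift,sensorSigma class-conditional Gaussian parameters.
#' @param seed master seed.
#' @return List of [NoduleSample-class] objects.
#' @export
makeDataset <- function(n, classBalance = 0.5, imageSize = 64,
                        spacingMm = 0.7, diameterRangeMm = c(6, 16),
                        benignSpiculation = c(0, 0.15),
                        malignantSpiculation = c(0.55, 0.95),
                        contrast = 45, noiseSigma = 15, background = 60,
                        gradientAmp = 0, sensorDim = 5, sensorShift = 3,
                        sensorSigma = 1, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (classBalance <= 0 || classBalance >= 1)
    stop("classBalance must lie strictly between 0 and 1")
  nMal <- round(n * classBalance)
  if (nMal < 1 || nMal > n - 1)
    stop("class balance unsatisfiable: one class would be empty")
  labels <- c(rep("malignant", nMal), rep("benign", n - nMal))
  lapply(seq_len(n), function(i) {
    si <- deriveSeed(seed, i)
    lab <- labels[i]
    pars <- withSeed(si, {
      list(diam = stats::runif(1, diameterRangeMm[1], diameterRangeMm[2]),
           spic = if (lab == "malignant")
             stats::runif(1, malignantSpiculation[1], malignantSpiculation[2])
           else stats::runif(1, benignSpiculation[1], benignSpiculation[2]),
           sensor = if (sensorDim > 0)
             stats::rnorm(sensorDim,
                          mean = if (lab == "malignant") sensorShift else 0,
                          sd = sensorSigma)
           else numeric(0))
    })
    sm <- makePhantom(phantomSpec(
      imageSize = imageSize, spacingMm = spacingMm,
      noduleDiameterMm = pars$diam, noduleClass = lab,
      spiculationLevel = pars$spic, contrast = contrast,
      noiseSigma = noiseSigma, background = background,
      gradientAmp = gradientAmp, seed = deriveSeed(si, 1)))
    sm@sensor <- pars$sensor
    sm@meta$id <- i
    sm
  })
}
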