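# GLCM texture, shape, intensity and semantic features of a nodule patch.

#' Gray-level co-occurrence matrix
#'
#' Quantizes the image to `nLevels` gray levels by min-max scaling (over
#' the masked region when a mask is given) and counts co-occurrences of
#' level pairs at the pixel offset `(di, dj)` (row, column displacement,
#' 0-based grid). With `symmetric = TRUE` the matrix is symmetrized by
#' adding its transpose before normalization. Entries are probabilities
#' summing to 1.
#'
#' @param image numeric matrix.
#' @param offset integer length-2 `(di, dj)`, not both zero.
#' @param nLevels number of gray levels (default 8).
#' @param symmetric symmetrize (default TRUE).
#' @param mask optional logical matrix; only pairs with both pixels inside
#'   the mask are counted and quantization breaks come from the masked
#'   range.
#' @return List of class `Glcm` with `matrix`, `offset`, `nLevels`,
#'   `symmetric`.
#' @export
computeGlcm <- function(image, offset = c(0L, 1L), nLevels = 8L,
                        symmetric = TRUE, mask = NULL) {
  stopifnot(is.matrix(image))
  di <- as.integer(offset[1]); dj <- as.integer(offset[2])
  if (di == 0 && dj == 0) stop("offset must be nonzero")
  ref <- if (is.null(mask)) image else image[mask]
  lo <- min(ref); hi <- max(ref)
  q <- if (hi > lo)
    pmin(floor((image - lo) / (hi - lo) * nLevels) + 1L, nLevels)
  else matrix(1L, nrow(image), ncol(image))
  q <- pmin(pmax(q, 1L), nLevels)          # out-of-range pixels clamped
  nr <- nrow(image); nc <- ncol(image)
  r1 <- max(1L, 1L - di):min(nr, nr - di)
  c1 <- max(1L, 1L - dj):min(nc, nc - dj)
  if (max(1L, 1L - di) > min(nr, nr - di) ||
      max(1L, 1L - dj) > min(nc, nc - dj))
    stop("offset larger than the image")
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + di, c1 + dj, drop = FALSE]
  keep <- rep(TRUE, length(i))
  if (!is.null(mask))
    keep <- mask[r1, c1, drop = FALSE] & mask[r1 + di, c1 + dj, drop = FALSE]
  if (!any(keep)) stop("no valid pixel pairs at this offset")
  counts <- matrix(tabulate((i[keep] - 1L) * nLevels + j[keep],
                            nbins = nLevels * nLevels),
                   nLevels, nLevels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(matrix = counts / sum(counts), offset = c(di, dj),
                 nLevels = as.integer(nLevels), symmetric = symmetric),
            class = "Glcm")
}

#' Haralick texture features of a GLCM
#'
#' Standard definitions over the co-occurrence probabilities `p(i, j)`
#' with level indices i, j:
#' contrast `sum p (i - j)^2`; correlation
#' `sum p (i - mu_i)(j - mu_j) / (sigma_i sigma_j)` (NA when a marginal
#' deviation vanishes, e.g. for a constant image); homogeneity
#' `sum p / (1 + |i - j|)`; entropy `-sum p log2 p` with `0 log 0 = 0`.
#'
#' @param glcm a [computeGlcm()] result.
#' @return Named list: `correlation`, `contrast`, `homogeneity`, `entropy`.
#' @export
textureFeatures <- function(glcm) {
  stopifnot(inherits(glcm, "Glcm"))
  p <- glcm$matrix
  n <- glcm$nLevels
  iM <- matrix(seq_len(n), n, n)
  jM <- t(iM)
  contrast <- sum(p * (iM - jM)^2)
  homogeneity <- sum(p / (1 + abs(iM - jM)))
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum(seq_len(n) * pi_); muj <- sum(seq_len(n) * pj)
  si <- sqrt(sum((seq_len(n) - mui)^2 * pi_))
  sj <- sqrt(sum((seq_len(n) - muj)^2 * pj))
  correlation <- if (si == 0 || sj == 0) NA_real_
    else sum(p * (iM - mui) * (jM - muj)) / (si * sj)
  list(correlation = correlation, contrast = contrast,
       homogeneity = homogeneity, entropy = entropy)
}

# clockwise 8-neighbourhood starting at North: N NE E SE S SW W NW
.mooreDirs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                     ncol = 2, byrow = TRUE)

#' Trace the outer boundary of a binary mask
#'
#' Moore-neighbour contour tracing, 8-connected, clockwise from north,
#' starting at the topmost-then-leftmost set pixel and terminating by
#' Jacob's criterion (re-entering the start with the initial backtrack).
#' Only the component containing the start pixel is traced.
#'
#' @param mask logical matrix with at least one TRUE pixel.
#' @return Integer matrix with columns `row`, `col`: the ordered closed
#'   boundary (first pixel not repeated at the end).
#' @export
traceBoundary <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  setAt <- function(r, c) inside(r, c) && mask[r, c]
  w <- which(mask, arr.ind = TRUE)
  s <- w[order(w[, 1], w[, 2])[1], ]
  cur <- s
  backIdx <- 7L                       # came from the West
  contour <- matrix(s, ncol = 2)
  startBack <- backIdx
  maxIter <- 8L * sum(mask) + 8L
  for (iter in seq_len(maxIter)) {
    found <- FALSE
    for (k in seq_len(8L)) {
      idx <- ((backIdx - 1L + k) %% 8L) + 1L
      p <- cur + .mooreDirs[idx, ]
      if (setAt(p[1], p[2])) {
        # new backtrack: the neighbour checked just before, seen from p
        prevIdx <- ((backIdx - 1L + k - 1L) %% 8L) + 1L
        prevPix <- cur + .mooreDirs[prevIdx, ]
        rel <- prevPix - p
        backIdx <- which(.mooreDirs[, 1] == rel[1] &
                           .mooreDirs[, 2] == rel[2])
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) break                  # isolated pixel
    if (cur[1] == s[1] && cur[2] == s[2] && backIdx == startBack) break
    contour <- rbind(contour, cur)
  }
  dimnames(contour) <- list(NULL, c("row", "col"))
  contour
}

#' Shape features of a nodule mask
#'
#' Area is the set-pixel count times the pixel area (spacing^2). The
#' perimeter Q is the Euclidean length of the closed traced boundary
#' polygon (see [traceBoundary()]) plus a half-pixel Minkowski offset
#' (pi * spacing) correcting the systematic underestimate of a
#' centre-traced outline; 1-2 pixel masks use the pixel-edge perimeter
#' (4 * spacing for a single pixel). The aspect ratio is the major/minor axis-length
#' ratio of the moment-matched ellipse (pixel covariance + 1/12 pixel
#' correction). Roundness and circularity are both isoperimetric ratios
#' `4 pi A / perimeter^2`; with the boundary-length convention used here
#' they coincide numerically. Discrete boundaries can push the ratio
#' slightly above 1 (documented tolerance 0.15).
#'
#' @param mask logical matrix (nonempty) or a [NoduleSample-class].
#' @param spacingMm mm per pixel (taken from the sample when one is given).
#' @return Named list: `area` (mm^2), `aspectRatio`, `roundness`,
#'   `perimeter` (mm), `circularity`.
#' @export
shapeFeatures <- function(mask, spacingMm = 1) {
  if (is(mask, "NoduleSample")) {
    spacingMm <- spacingMm(mask)
    mask <- sampleMask(mask)
  }
  if (!any(mask)) stop("empty mask")
  npix <- sum(mask)
  area <- npix * spacingMm^2
  contour <- traceBoundary(mask)
  if (nrow(contour) < 3) {
    # degenerate 1-2 pixel regions: crack (pixel-edge) perimeter
    Q <- (2 * npix + 2) * spacingMm
  } else {
    closed <- rbind(contour, contour[1, ])
    # pixel-centre polygon length plus the half-pixel Minkowski offset
    # (a boundary traced through centres underestimates the true outline
    # by ~ 2 pi * 0.5 px for convex shapes)
    Q <- (sum(sqrt(rowSums(diff(closed)^2))) + pi) * spacingMm
  }
  w <- which(mask, arr.ind = TRUE)
  cv <- if (nrow(w) == 1) diag(1 / 12, 2)
    else stats::cov(w) * (nrow(w) - 1) / nrow(w) +
      diag(1 / 12, 2)                # population cov + pixel variance
  ev <- sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE)
  aspectRatio <- sqrt(ev[1] / ev[2])
  circ <- 4 * pi * area / Q^2
  list(area = area, aspectRatio = aspectRatio, roundness = circ,
       perimeter = Q, circularity = circ)
}

#' Intensity features of a masked region
#'
#' Moments are taken over the empirical intensity distribution of the
#' masked pixels: mean, variance (2nd central moment), skewness and
#' kurtosis as the *raw* 3rd and 4th central moments (the tabled forms,
#' not normalized), uniformity `sum H^2` over a `nBins`-bin normalized
#' histogram of the region, and smoothness `1 - 1 / (1 + variance)`.
#' Intensities enter on their native scale; smoothness therefore
#' saturates quickly on 8-bit-like data.
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape, nonempty.
#' @param nBins histogram bins for uniformity (default 256).
#' @return Named list: `uniformity`, `mean`, `variance`, `kurtosis`,
#'   `skewness`, `smoothness`.
#' @export
intensityFeatures <- function(image, mask, nBins = 256L) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  v <- image[mask]
  if (!length(v)) stop("empty region")
  m <- mean(v)
  varv <- mean((v - m)^2)
  skew <- mean((v - m)^3)
  kurt <- mean((v - m)^4)
  h <- frameHistogram(v, nBins = nBins)
  uniformity <- sum(h$probs^2)
  list(uniformity = uniformity, mean = m, variance = varv,
       kurtosis = kurt, skewness = skew,
       smoothness = 1 - 1 / (1 + varv))
}

.sizeBins <- c("<4 mm", "4-7 mm", "8-20 mm", ">20 mm")

#' Semantic (high-level) nodule attributes
#'
#' Equivalent-circle diameter `2 sqrt(A / pi)` in mm; a size bin with cut
#' points 4, 8 and 20 mm, boundaries assigned to the lower bin (the
#' printed gap between the "4-7 mm" and "8-20 mm" bins is closed at
#' 8 mm); a spiculation score `clamp01(1 - circularity)`; a morphology
#' label from documented thresholds (spiculation >= 0.45 "Irregular",
#' >= 0.2 "Spiculated", else aspect ratio >= 1.25 "Lobulated", else
#' "Smooth" -- digitization floors the score of perfectly smooth shapes
#' around 0.1-0.15, so the cut sits above that floor); and the
#' upper-lobe flag passed through from metadata (it is not computable
#' from a patch).
#'
#' @param mask logical matrix or [NoduleSample-class].
#' @param spacingMm mm per pixel.
#' @param upperLobe logical or NA, passed through.
#' @return Named list: `sizeBin`, `diameterMm`, `spiculation`,
#'   `upperLobe`, `morphology`.
#' @export
semanticFeatures <- function(mask, spacingMm = 1, upperLobe = NA) {
  if (is(mask, "NoduleSample")) {
    spacingMm <- spacingMm(mask)
    upperLobe <- mask@meta$upperLobe %||% NA
    mask <- sampleMask(mask)
  }
  if (is.null(spacingMm) || !is.finite(spacingMm))
    stop("spacing is required for semantic features")
  sf <- shapeFeatures(mask, spacingMm)
  d <- 2 * sqrt(sf$area / pi)
  sizeBin <- .sizeBins[findInterval(d, c(4, 8, 20), left.open = TRUE) + 1]
  spic <- clamp01(1 - sf$circularity)
  morphology <- if (spic >= 0.45) "Irregular"
    else if (spic >= 0.2) "Spiculated"
    else if (sf$aspectRatio >= 1.25) "Lobulated"
    else "Smooth"
  list(sizeBin = sizeBin, diameterMm = d, spiculation = spic,
       upperLobe = upperLobe, morphology = morphology)
}

.glcmOffsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Full feature vector of a nodule sample
#'
#' Concatenates the texture block (GLCM features averaged over the four
#' standard offsets (0,1), (1,0), (1,1), (1,-1), computed over the masked
#' region), the shape block, the intensity block, the semantic block and,
#' when present and requested, the sensor record. Deterministic.
#'
#' @param sample a [NoduleSample-class].
#' @param glcmLevels gray levels for the GLCM (default 8).
#' @param includeSensor append the sensor record (default TRUE).
#' @return List of class `FeatureVector` with blocks `texture`, `shape`,
#'   `intensity`, `semantic`, `sensor`. Use [featureVectorAsNumeric()] for
#'   a flat named vector.
#' @export
extractFeatureVector <- function(sample, glcmLevels = 8L,
                                 includeSensor = TRUE) {
  stopifnot(is(sample, "NoduleSample"))
  img <- sampleImage(sample)
  msk <- sampleMask(sample)
  tex <- lapply(.glcmOffsets, function(off)
    textureFeatures(computeGlcm(img, off, nLevels = glcmLevels, mask = msk)))
  texture <- lapply(stats::setNames(nm = names(tex[[1]])), function(nm)
    mean(vapply(tex, `[[`, 1, nm)))
  structure(list(
    texture = texture,
    shape = shapeFeatures(msk, spacingMm(sample)),
    intensity = intensityFeatures(img, msk),
    semantic = semanticFeatures(sample),
    sensor = if (includeSensor) sensorValues(sample) else numeric(0)),
    class = "FeatureVector")
}

#' Flatten a FeatureVector to a named numeric vector
#'
#' Categorical semantic entries are coded numerically: the size bin as
#' 1..4 in increasing size order, morphology as Smooth = 1, Lobulated = 2,
#' Spiculated = 3, Irregular = 4, and the upper-lobe flag as 1/0 with 0.5
#' for unknown.
#'
#' @param fv a [extractFeatureVector()] result.
#' @return Named numeric vector matching [featureSchema()].
#' @export
featureVectorAsNumeric <- function(fv) {
  stopifnot(inherits(fv, "FeatureVector"))
  sem <- fv$semantic
  morphCode <- match(sem$morphology,
                     c("Smooth", "Lobulated", "Spiculated", "Irregular"))
  ul <- if (is.na(sem$upperLobe)) 0.5 else as.numeric(sem$upperLobe)
  out <- c(unlist(fv$texture), unlist(fv$shape), unlist(fv$intensity),
           sizeBin = match(sem$sizeBin, .sizeBins),
           diameterMm = sem$diameterMm, spiculation = sem$spiculation,
           upperLobe = ul, morphology = morphCode)
  if (length(fv$sensor))
    out <- c(out, stats::setNames(fv$sensor,
                                  paste0("sensor", seq_along(fv$sensor))))
  names(out)[1:4] <- paste0("texture.", c("correlation", "contrast",
                                          "homogeneity", "entropy"))
  out
}

#' Names of the flattened feature schema
#'
#' @param sensorDim sensor record length (default 0).
#' @return Character vector of column names.
#' @export
featureSchema <- function(sensorDim = 0L) {
  nm <- c(paste0("texture.", c("correlation", "contrast", "homogeneity",
                               "entropy")),
          c("area", "aspectRatio", "roundness", "perimeter", "circularity"),
          c("uniformity", "mean", "variance", "kurtosis", "skewness",
            "smoothness"),
          c("sizeBin", "diameterMm", "spiculation", "upperLobe",
            "morphology"))
  if (sensorDim > 0) nm <- c(nm, paste0("sensor", seq_len(sensorDim)))
  nm
}

#' Feature matrix for a list of samples
#'
#' @param samples list of [NoduleSample-class].
#' @param ... passed to [extractFeatureVector()].
#' @return Numeric matrix, one row per sample, columns per
#'   [featureSchema()]; row names are sample indices.
#' @export
featureMatrix <- function(samples, ...) {
  rows <- lapply(samples, function(s)
    featureVectorAsNumeric(extractFeatureVector(s, ...)))
  out <- do.call(rbind, rows)
  rownames(out) <- seq_along(samples)
  out
}
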