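# Intensity normalization and histogram-entropy redundant-frame filtering.

#' Z-score intensity normalization rescaled to [0, 1]
#'
#' Standardizes intensities with the population standard deviation,
#' `z = (x - mean) / sd`, then rescales affinely so the minimum maps to 0
#' and the maximum to 1. (The plain Z-score does not land in [0, 1]; the
#' min-max rescale preserves both the standardization and the stated
#' output range. The two steps together are invariant to any positive
#' affine transform of the input.) A constant image maps to all 0.5.
#'
#' @param image numeric matrix or array.
#' @return Same shape, values in [0, 1].
#' @examples
#' zscoreNormalize(c(0, 1, 2))  # 0, 0.5, 1
#' @export
zscoreNormalize <- function(image) {
  if (length(image) == 0) stop("empty image")
  x <- asGrid(image)
  stopIfNotFinite(x, "image")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    x[] <- 0.5
    return(x)
  }
  z <- (x - mean(x)) / s
  (z - min(z)) / (max(z) - min(z))
}

#' Normalized intensity histogram of a frame
#'
#' Equal-width bins over `range` (default the frame's min/max), counts
#' normalized to probabilities. Values equal to the upper bound fall in
#' the last bin; values outside the range are ignored (an error is raised
#' if no pixel lies inside).
#'
#' @param frame numeric matrix or vector.
#' @param nBins number of bins (default 256, >= 2).
#' @param range length-2 numeric, `lo < hi`.
#' @return List of class `IntensityHistogram` with `probs`, `nBins`,
#'   `range`.
#' @export
frameHistogram <- function(frame, nBins = 256L, range = NULL) {
  x <- as.vector(asGrid(frame))
  if (nBins < 2) stop("nBins must be >= 2")
  if (is.null(range)) range <- c(min(x), max(x))
  lo <- range[1]; hi <- range[2]
  if (!(lo < hi)) {
    if (lo == hi && all(x == lo)) {
      # degenerate constant frame: all mass in the first bin
      probs <- c(1, rep(0, nBins - 1))
      return(structure(list(probs = probs, nBins = as.integer(nBins),
                            range = c(lo, hi)),
                       class = "IntensityHistogram"))
    }
    stop("range must satisfy lo < hi")
  }
  inside <- x >= lo & x <= hi
  if (!any(inside)) stop("all pixels fall outside the histogram range")
  x <- x[inside]
  idx <- pmin(floor((x - lo) / (hi - lo) * nBins) + 1, nBins)
  probs <- tabulate(idx, nbins = nBins) / length(x)
  structure(list(probs = probs, nBins = as.integer(nBins),
                 range = c(lo, hi)),
            class = "IntensityHistogram")
}

#' Relative entropy (and its square root) between two histograms
#'
#' Kullback-Leibler divergence in bits,
#' `D_RE = sum P(k) log2(P(k) / Q(k))`, with an epsilon floor on both
#' distributions so empty bins keep the divergence finite; tiny negative
#' round-off is clamped to zero. The Square Root of Relative Entropy is
#' `D_SRRE = sqrt(D_RE)`.
#'
#' @param p,q `IntensityHistogram` objects (see [frameHistogram()]) or
#'   plain probability vectors of equal length.
#' @param eps floor applied to both distributions' bins (default 1e-12).
#' @return List of class `FrameDistance` with `dRE` and `dSRRE`.
#' @examples
#' relativeEntropy(c(0.5, 0.5), c(0.25, 0.75))$dRE  # 0.20752 bits
#' @export
relativeEntropy <- function(p, q, eps = 1e-12) {
  pv <- if (inherits(p, "IntensityHistogram")) p$probs else as.numeric(p)
  qv <- if (inherits(q, "IntensityHistogram")) q$probs else as.numeric(q)
  if (length(pv) != length(qv)) stop("bin-count mismatch")
  pv <- pmax(pv, eps)
  qv <- pmax(qv, eps)
  dRE <- max(sum(pv * log2(pv / qv)), 0)
  structure(list(dRE = dRE, dSRRE = sqrt(dRE)), class = "FrameDistance")
}

#' Eliminate redundant frames by relative-entropy distance
#'
#' Scans an ordered frame sequence and drops every frame whose histogram
#' distance to the last *kept* frame falls below `threshold`, so runs of
#' near-duplicates collapse onto their first representative. The first
#' frame is always kept. Distances are [relativeEntropy()] on
#' `nBins`-bin histograms over a common intensity range (the global
#' min/max of the sequence unless given).
#'
#' @param frames list of numeric matrices, or a 3-D array sliced along its
#'   third dimension.
#' @param threshold nonnegative distance threshold.
#' @param nBins histogram bins (default 256).
#' @param useSqrt if TRUE compare the Square Root of Relative Entropy
#'   instead of the Relative Entropy.
#' @param range optional common histogram range.
#' @return Integer vector of kept frame indices (1-based), always starting
#'   at 1.
#' @export
eliminateRedundantFrames <- function(frames, threshold, nBins = 256L,
                                     useSqrt = FALSE, range = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!length(frames)) stop("at least one frame required")
  if (is.null(range))
    range <- c(min(vapply(frames, min, 1)), max(vapply(frames, max, 1)))
  hist1 <- function(f) frameHistogram(f, nBins = nBins, range = range)
  kept <- 1L
  lastHist <- hist1(frames[[1L]])
  for (i in seq_along(frames)[-1L]) {
    h <- hist1(frames[[i]])
    d <- relativeEntropy(lastHist, h)
    dist <- if (useSqrt) d$dSRRE else d$dRE
    if (dist >= threshold) {
      kept <- c(kept, i)
      lastHist <- h
    }
  }
  kept
}
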