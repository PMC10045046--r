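# One-level separable orthogonal wavelet transform with periodized
# boundaries. Hand-written: the subband machinery is the core of the
# denoiser and no wavelet package is available in the target library.

# Scaling (low-pass) filters. "d8" is the 8-tap Daubechies filter with four
# vanishing moments; "haar" the 2-tap Haar filter. Both are orthonormal:
# sum h^2 = 1, even shifts orthogonal.
.waveletFilters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  d8 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
         -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
         0.032883011666982945, -0.010597401784997278)
)

waveletFilter <- function(waveletName) {
  h <- .waveletFilters[[waveletName]]
  if (is.null(h)) stop("unknown wavelet: '", waveletName, "'")
  h
}

# n x n orthogonal one-level analysis matrix for even n: first n/2 rows are
# circular double-shifts of the low-pass filter h, last n/2 rows of the
# quadrature mirror g[m] = (-1)^m h[L-1-m]. Aliasing of taps beyond n keeps
# the matrix orthogonal for any even n.
.analysisMatrix <- function(n, h) {
  stopifnot(n %% 2 == 0)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  A <- matrix(0, n, n)
  half <- n / 2
  for (k in seq_len(half)) {
    for (m in seq_len(L)) {
      j <- ((2 * (k - 1) + m - 1) %% n) + 1
      A[k, j] <- A[k, j] + h[m]
      A[half + k, j] <- A[half + k, j] + g[m]
    }
  }
  A
}

# Apply matrix M along dimension d of array x.
.applyAlongDim <- function(x, M, d) {
  dims <- dim(x)
  nd <- length(dims)
  perm <- c(d, setdiff(seq_len(nd), d))
  xp <- aperm(x, perm)
  m <- matrix(xp, dims[d], prod(dims[-d]))
  y <- M %*% m
  yp <- array(y, dim = c(nrow(M), dims[-d]))
  aperm(yp, order(perm))
}

.padEven <- function(x) {
  dims <- dim(x)
  pad <- dims %% 2L
  if (!any(pad == 1L)) return(x)
  out <- x
  for (d in which(pad == 1L)) {
    dd <- dim(out)
    idx <- lapply(dd, seq_len)
    idx[[d]] <- dd[d]          # replicate the trailing slab
    edge <- do.call(`[`, c(list(out), idx, list(drop = FALSE)))
    out <- .abind(out, edge, d)
  }
  out
}

# minimal bind of two arrays along dimension d
.abind <- function(a, b, d) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  perm <- c(setdiff(seq_len(nd), d), d)
  am <- matrix(aperm(a, perm), ncol = da[d])
  bm <- matrix(aperm(b, perm), ncol = db[d])
  cm <- cbind(am, bm)
  out <- array(cm, dim = c(da[-d], da[d] + db[d]))
  aperm(out, order(perm))
}

#' One-level wavelet decomposition into subbands
#'
#' Applies a one-level separable orthogonal wavelet transform with
#' periodized boundaries along every array dimension, producing 4 subbands
#' (LL, LH, HL, HH) for a 2-D slice or 8 (LLL ... HHH) for a 3-D volume.
#' Odd dimensions are padded by edge replication before the transform and
#' cropped again on reconstruction, so subband shapes are `ceiling(dim/2)`.
#' The transform is orthonormal: energy is conserved and
#' [waveletReconstruct()] inverts it to machine precision.
#'
#' @param volume a [CtVolume-class], matrix or 3-D array with all
#'   dimensions >= 2.
#' @param waveletName "d8" (default, 8-tap orthogonal Daubechies) or "haar".
#' @return A [SubbandSet-class].
#' @examples
#' sb <- waveletDecompose(array(rnorm(16^3), dim = c(16, 16, 16)))
#' names(subbands(sb))
#' @export
waveletDecompose <- function(volume, waveletName = "d8") {
  x <- asGrid(volume)
  if (is.null(dim(x))) stop("input must be a matrix or array")
  stopIfNotFinite(x, "volume")
  dims <- dim(x)
  if (any(dims < 2)) stop("every dimension must be >= 2")
  h <- waveletFilter(waveletName)
  orig <- as.integer(dims)
  xp <- .padEven(x)
  pd <- dim(xp)
  nd <- length(pd)
  for (d in seq_len(nd))
    xp <- .applyAlongDim(xp, .analysisMatrix(pd[d], h), d)
  half <- pd %/% 2L
  lows <- lapply(half, seq_len)
  highs <- lapply(seq_len(nd), function(d) half[d] + seq_len(half[d]))
  combos <- expand.grid(rep(list(c("L", "H")), nd),
                        stringsAsFactors = FALSE)
  sb <- list()
  for (r in seq_len(nrow(combos))) {
    lt <- as.character(unlist(combos[r, ]))  # lt[d] = branch along dim d
    idx <- lapply(seq_len(nd), function(d)
      if (lt[d] == "L") lows[[d]] else highs[[d]])
    nm <- paste(lt, collapse = "")
    sb[[nm]] <- do.call(`[`, c(list(xp), idx, list(drop = FALSE)))
  }
  new("SubbandSet", subbands = sb, waveletName = waveletName,
      originalShape = orig)
}

#' Reconstruct a volume from its wavelet subbands
#'
#' Inverse of [waveletDecompose()]; exact to machine precision when the
#' subbands are untouched.
#'
#' @param subbandSet a [SubbandSet-class].
#' @return A matrix or array with the original input shape.
#' @export
waveletReconstruct <- function(subbandSet) {
  stopifnot(is(subbandSet, "SubbandSet"))
  sb <- subbandSet@subbands
  h <- waveletFilter(subbandSet@waveletName)
  halfDims <- dim(sb[[1L]])
  nd <- length(halfDims)
  pd <- 2L * halfDims
  x <- array(0, dim = pd)
  lows <- lapply(halfDims, seq_len)
  highs <- lapply(seq_len(nd), function(d) halfDims[d] + seq_len(halfDims[d]))
  for (nm in names(sb)) {
    lt <- strsplit(nm, "")[[1L]]
    idx <- lapply(seq_len(nd), function(d)
      if (lt[d] == "L") lows[[d]] else highs[[d]])
    x <- do.call(`[<-`, c(list(x), idx, list(sb[[nm]])))
  }
  for (d in seq_len(nd))
    x <- .applyAlongDim(x, t(.analysisMatrix(pd[d], h)), d)
  orig <- subbandSet@originalShape
  idx <- lapply(orig, seq_len)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}
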