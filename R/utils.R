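# internal helpers shared across modules

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Counter-based per-item seed derivation: datasets are extensible without
# reshuffling earlier items. Kept below 2^31 - 1.
deriveSeed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + as.numeric(counter) * 104729) %%
               2147483647)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # arg order keeps dim attributes

# Bilinear resize of a matrix to outH x outW (pixel-centre alignment).
resizeBilinear <- function(mat, outH, outW) {
  inH <- nrow(mat); inW <- ncol(mat)
  if (inH == outH && inW == outW) return(mat)
  ry <- if (outH > 1) (inH - 1) / (outH - 1) else 0
  rx <- if (outW > 1) (inW - 1) / (outW - 1) else 0
  y <- (seq_len(outH) - 1) * ry
  x <- (seq_len(outW) - 1) * rx
  y0 <- pmin(floor(y), inH - 1); y1 <- pmin(y0 + 1, inH - 1)
  x0 <- pmin(floor(x), inW - 1); x1 <- pmin(x0 + 1, inW - 1)
  wy <- y - y0; wx <- x - x0
  a <- mat[y0 + 1, x0 + 1, drop = FALSE]
  b <- mat[y0 + 1, x1 + 1, drop = FALSE]
  cc <- mat[y1 + 1, x0 + 1, drop = FALSE]
  d <- mat[y1 + 1, x1 + 1, drop = FALSE]
  wyM <- matrix(wy, outH, outW)
  wxM <- matrix(wx, outH, outW, byrow = TRUE)
  (1 - wyM) * ((1 - wxM) * a + wxM * b) + wyM * ((1 - wxM) * cc + wxM * d)
}

# Coerce CtVolume / matrix / array input to a plain array, remembering class.
asGrid <- function(x) {
  if (is(x, "CtVolume")) voxels(x) else x
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must contain only finite values")
}
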