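# Independent oracles and small fixture builders used across the suite.

# Brute-force GLCM: explicit double loop over all pixel pairs.
bruteGlcm <- function(image, offset, nLevels, symmetric) {
  lo <- min(image); hi <- max(image)
  q <- if (hi > lo)
    pmin(floor((image - lo) / (hi - lo) * nLevels) + 1, nLevels)
  else matrix(1, nrow(image), ncol(image))
  cnt <- matrix(0, nLevels, nLevels)
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 >= 1 && r2 <= nrow(image) && c2 >= 1 && c2 <= ncol(image))
      cnt[q[r, c], q[r2, c2]] <- cnt[q[r, c], q[r2, c2]] + 1
  }
  if (symmetric) cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

# Brute-force Haralick features from a GLCM probability matrix, written as
# plain double loops (independent of the vectorized implementation).
bruteTexture <- function(p) {
  n <- nrow(p)
  mui <- 0; muj <- 0
  for (i in 1:n) for (j in 1:n) { mui <- mui + i * p[i, j]
                                  muj <- muj + j * p[i, j] }
  si2 <- 0; sj2 <- 0; contrast <- 0; homog <- 0; ent <- 0; xmom <- 0
  for (i in 1:n) for (j in 1:n) {
    si2 <- si2 + (i - mui)^2 * p[i, j]
    sj2 <- sj2 + (j - muj)^2 * p[i, j]
    contrast <- contrast + p[i, j] * (i - j)^2
    homog <- homog + p[i, j] / (1 + abs(i - j))
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    xmom <- xmom + p[i, j] * (i - mui) * (j - muj)
  }
  list(correlation = if (si2 == 0 || sj2 == 0) NA_real_
                     else xmom / sqrt(si2 * sj2),
       contrast = contrast, homogeneity = homog, entropy = ent)
}

# Digital disk mask of radius r (pixels) on a square grid.
mkDisk <- function(r, n = 2 * ceiling(r) + 9) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2) <= r)
}

# Square mask of side s centred on a grid with margin.
mkSquare <- function(s, margin = 8) {
  n <- s + 2 * margin
  m <- matrix(FALSE, n, n)
  m[(margin + 1):(margin + s), (margin + 1):(margin + s)] <- TRUE
  m
}

# Shared separable cohort for the classifier tests (built once per run).
classifierCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeDataset(120, 0.5, seed = 11)
    cache
  }
})
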