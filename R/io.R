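# Plain-text PGM and 16-bit PNG image I/O plus dataset export.

#' Write a grayscale image as plain-text PGM (P2)
#'
#' Intensities are linearly mapped from `range` onto 0..maxVal integers.
#' PGM P2 is plain text, which keeps fixtures and exports human-readable
#' and binary-free.
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param maxVal maximum gray value (default 65535, 16-bit).
#' @param range intensity range mapped onto 0..maxVal (default the image
#'   min/max; a constant image maps to 0).
#' @return Invisibly, the scaling used (list with `range`, `maxVal`).
#' @export
writePgm <- function(image, path, maxVal = 65535L, range = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(range)) range <- c(min(image), max(image))
  span <- range[2] - range[1]
  q <- if (span > 0)
    round((pmin(pmax(image, range[1]), range[2]) - range[1]) / span * maxVal)
  else matrix(0L, nrow(image), ncol(image))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)),
               as.character(maxVal)), con)
  # one image row per line, row-major as PGM expects
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(list(range = range, maxVal = maxVal))
}

#' Read a plain-text PGM (P2) image
#'
#' @param path PGM file.
#' @param range optional intensity range to map 0..maxVal back onto; by
#'   default raw 0..maxVal values are returned.
#' @return Numeric matrix.
#' @export
readPgm <- function(path, range = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tok <- scan(text = paste(lines[-1], collapse = " "), what = numeric(),
              quiet = TRUE)
  if (trimws(lines[1]) != "P2") stop("not a plain PGM (P2) file")
  w <- tok[1]; h <- tok[2]; maxVal <- tok[3]
  px <- tok[-(1:3)]
  if (length(px) != w * h) stop("pixel count mismatch in PGM")
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  if (!is.null(range)) m <- m / maxVal * (range[2] - range[1]) + range[1]
  m
}

#' Write a grayscale image as 16-bit PNG
#'
#' @inheritParams writePgm
#' @return Invisibly, the scaling used.
#' @export
writePng16 <- function(image, path, range = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(range)) range <- c(min(image), max(image))
  span <- range[2] - range[1]
  q <- if (span > 0)
    (pmin(pmax(image, range[1]), range[2]) - range[1]) / span
  else matrix(0, nrow(image), ncol(image))
  png::writePNG(q, path, bitdepth = 16)
  invisible(list(range = range, maxVal = 65535L))
}

#' Export a phantom dataset to disk
#'
#' Writes one image and one mask file per sample (PNG 16-bit or plain-text
#' PGM), a `manifest.csv` indexing the set (id, files, label, spacing,
#' intensity range, semantic attributes) and, when sensor records are
#' present, their values as `sensor1..sensorK` manifest columns.
#'
#' @param samples list of [NoduleSample-class].
#' @param dir output directory (created if needed).
#' @param format "png" or "pgm".
#' @return Invisibly, the manifest data.frame.
#' @export
writeDataset <- function(samples, dir, format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writer <- if (format == "png") writePng16 else writePgm
  ext <- format
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    imgFile <- sprintf("image_%04d.%s", i, ext)
    maskFile <- sprintf("mask_%04d.%s", i, ext)
    rng <- c(min(sampleImage(s)), max(sampleImage(s)))
    writer(sampleImage(s), file.path(dir, imgFile), range = rng)
    writer(sampleMask(s) * 1, file.path(dir, maskFile), range = c(0, 1))
    sem <- semanticFeatures(s)
    row <- data.frame(id = i, image = imgFile, mask = maskFile,
                      label = sampleLabel(s), spacingMm = spacingMm(s),
                      intensityLo = rng[1], intensityHi = rng[2],
                      diameterMm = sem$diameterMm, sizeBin = sem$sizeBin,
                      spiculation = sem$spiculation,
                      morphology = sem$morphology,
                      stringsAsFactors = FALSE)
    sens <- sensorValues(s)
    if (length(sens))
      row <- cbind(row, stats::setNames(as.data.frame(t(sens)),
                                        paste0("sensor", seq_along(sens))))
    row
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
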