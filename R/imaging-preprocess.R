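# Cross-device image normalization: pixel geometry, magnification matching,
# CLAHE, grayscale conversion, mask-centered cropping, and Otsu-based
# fluorescence-area quantification. Images are plain numeric/integer
# matrices in native intensity units (0..255 or 0..65535); EBImage backs
# interpolation, CLAHE, Otsu and file I/O.

.maxVal <- function(image, bitDepth = NULL) {
  if (!is.null(bitDepth)) {
    if (!bitDepth %in% c(8, 16)) stop("bitDepth must be 8 or 16")
    return(2^bitDepth - 1)
  }
  if (max(image) > 255) 65535 else 255
}

#' Micrometers per pixel from field of view and sensor size
#'
#' @param fovUm field of view in micrometers (one axis).
#' @param sizePx image size in pixels along the same axis.
#' @return `fovUm / sizePx`.
#' @examples
#' computePixelSize(291, 904) # ~0.322, a 20x brightfield device
#' computePixelSize(85, 448)  # ~0.19, a 60x holotomographic device
#' @export
computePixelSize <- function(fovUm, sizePx) {
  if (any(fovUm <= 0) || any(sizePx <= 0))
    stop("field of view and pixel size must be positive")
  fovUm / sizePx
}

#' Pixel geometry of an imaging device
#'
#' @param fovUm length-2 field of view (width, height) in micrometers.
#' @param sizePx length-2 image size (width, height) in pixels.
#' @return List with `fovUm`, `sizePx`, `umPerPx` (per axis) and the mean
#'   `umPerPxMean`; warns when the two axes differ by more than 1%.
#' @export
pixelGeometry <- function(fovUm, sizePx) {
  stopifnot(length(fovUm) == 2L, length(sizePx) == 2L)
  upp <- computePixelSize(fovUm, sizePx)
  if (abs(upp[1] - upp[2]) / mean(upp) > 0.01)
    warning("pixel size is anisotropic beyond 1%: ",
            paste(signif(upp, 4), collapse = " vs "))
  list(fovUm = fovUm, sizePx = sizePx, umPerPx = upp,
       umPerPxMean = mean(upp))
}

#' Magnification-matching scale factor
#'
#' The factor that rescales a source image so its pixel size matches a
#' destination device: source pixel size divided by destination pixel size.
#' A factor below 1 downscales the source.
#'
#' @param srcUmPerPx,dstUmPerPx micrometers per pixel of source and
#'   destination.
#' @return `srcUmPerPx / dstUmPerPx`.
#' @examples
#' scaleFactor(computePixelSize(85, 448), computePixelSize(291, 904)) # 0.59
#' @export
scaleFactor <- function(srcUmPerPx, dstUmPerPx) {
  if (any(srcUmPerPx <= 0) || any(dstUmPerPx <= 0))
    stop("pixel sizes must be positive")
  srcUmPerPx / dstUmPerPx
}

#' Rescale an image by a magnification factor
#'
#' Bilinear interpolation to `round(dim * factor)`; a factor of exactly 1
#' returns a pixel-identical copy.
#'
#' @param image single-channel numeric matrix.
#' @param factor positive scale factor.
#' @return Rescaled matrix.
#' @examples
#' dim(rescaleImage(matrix(0, 448, 448), 0.59)) # 264 x 264
#' @export
rescaleImage <- function(image, factor) {
  if (factor <= 0) stop("scale factor must be positive")
  image <- as.matrix(image)
  if (factor == 1) return(image)
  nd <- round(dim(image) * factor)
  if (any(nd < 1)) stop("rescaled dimension would fall below 1 pixel")
  out <- EBImage::resize(image, w = nd[1L], h = nd[2L], filter = "bilinear")
  matrix(as.numeric(out), nd[1L], nd[2L])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Standard CLAHE on a single-channel image, deterministic, preserving shape
#' and integer storage. A constant image (no contrast to equalize) is
#' returned unchanged. RGB input must be converted with [toGrayscale()]
#' first.
#'
#' @param image single-channel numeric matrix (8- or 16-bit range).
#' @param clipLimit contrast clip limit (default 2).
#' @param tileGrid length-2 tile grid (default 8 x 8).
#' @param bitDepth 8 or 16; inferred from the intensity range when omitted.
#' @return Equalized matrix, same shape, integer values in the input depth.
#' @export
claheNormalize <- function(image, clipLimit = 2, tileGrid = c(8L, 8L),
                           bitDepth = NULL) {
  if (length(dim(image)) == 3L)
    stop("RGB input: convert with toGrayscale() before CLAHE")
  image <- as.matrix(image)
  mv <- .maxVal(image, bitDepth)
  if (diff(range(image)) == 0) return(image)
  # the equalizer needs dimensions divisible by the tile grid: pad by edge
  # replication and crop the result back
  nr <- nrow(image)
  nc <- ncol(image)
  pr <- (tileGrid[1L] - nr %% tileGrid[1L]) %% tileGrid[1L]
  pc <- (tileGrid[2L] - nc %% tileGrid[2L]) %% tileGrid[2L]
  padded <- image[c(seq_len(nr), rep(nr, pr)),
                  c(seq_len(nc), rep(nc, pc)), drop = FALSE]
  out <- EBImage::clahe(padded / mv, nx = tileGrid[1L], ny = tileGrid[2L],
                        limit = clipLimit)
  out <- matrix(as.numeric(out), nr + pr, nc + pc)[seq_len(nr),
                                                   seq_len(nc)]
  matrix(as.integer(pmin(mv, pmax(0, round(out * mv)))), nr, nc)
}

#' Luminance-weighted grayscale conversion
#'
#' ITU-R 601 weights: `0.299 R + 0.587 G + 0.114 B`. A single-channel input
#' is returned unchanged.
#'
#' @param image h x w x 3 numeric array, or a matrix.
#' @return Single-channel matrix.
#' @export
toGrayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("expected a h x w x 3 array or a matrix")
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Fixed-size crops around cell-mask centers
#'
#' Cuts a `size x size` window around each center with the even-size
#' convention that the center pixel lands at zero-based index `size / 2`
#' (row and column). Regions outside the source are zero-padded and the
#' padded fraction is recorded so heavily padded crops can be filtered
#' downstream. Centers outside the image are skipped with a warning.
#'
#' @param image single-channel numeric matrix.
#' @param centers n x 2 matrix of (row, col) centers, 1-based.
#' @param size crop side in pixels (default 224).
#' @param sourceId identifier stored with each crop.
#' @return List of crops, each a list with `image` (`size x size`),
#'   `center`, `sourceId`, `padFraction`.
#' @export
cropAroundCenters <- function(image, centers, size = 224L,
                              sourceId = "image") {
  image <- as.matrix(image)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  size <- as.integer(size)
  half <- size %/% 2L
  crops <- list()
  for (i in seq_len(nrow(centers))) {
    r <- round(centers[i, 1L])
    c <- round(centers[i, 2L])
    if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image)) {
      warning("center ", i, " lies outside the image; skipped")
      next
    }
    rows <- (r - half):(r + half - 1L)
    cols <- (c - half):(c + half - 1L)
    crop <- matrix(0, size, size)
    okr <- rows >= 1 & rows <= nrow(image)
    okc <- cols >= 1 & cols <= ncol(image)
    crop[which(okr), which(okc)] <-
      image[rows[okr], cols[okc], drop = FALSE]
    crops[[length(crops) + 1L]] <- list(
      image = crop,
      center = c(row = r, col = c),
      sourceId = sourceId,
      padFraction = 1 - sum(okr) * sum(okc) / size^2
    )
  }
  crops
}

# Canonical Otsu: argmax over thresholds t of the between-class variance
# w0(t) * w1(t) * (mu0(t) - mu1(t))^2 with class 0 = gray values <= t.
# Cumulative-sum form over the integer histogram; all intermediate sums are
# integers, so the curve is computed exactly in double precision.
.otsuThreshold <- function(image, maxVal) {
  v <- as.integer(round(image))
  h <- as.numeric(tabulate(v + 1L, nbins = maxVal + 1L))
  g <- as.numeric(0:maxVal)
  w0 <- cumsum(h)
  N <- w0[length(w0)]
  m0 <- cumsum(g * h)
  M <- m0[length(m0)]
  # sigma_B^2(t) proportional to (M*w0 - m0*N)^2 / (w0*(N - w0))
  num <- (M * w0 - m0 * N)^2
  den <- w0 * (N - w0)
  crit <- ifelse(den > 0, num / den, -Inf)
  crit <- crit[seq_len(maxVal)] # t in 0..maxVal-1
  as.integer(which.max(crit) - 1L)
}

#' Otsu threshold and fluorescence-area quantification
#'
#' Computes the Otsu threshold (the gray level maximizing the inter-class
#' variance of the intensity histogram), builds the binary mask of
#' above-threshold pixels, labels its 8-connected components and sums their
#' areas — the standard readout for total fluorescence-marker area per
#' frame.
#'
#' @param image single-channel integer-valued matrix.
#' @param bitDepth 8 or 16; inferred when omitted.
#' @return List with `threshold` (integer gray level; foreground is
#'   `image > threshold`), `mask` (logical matrix), `totalAreaPx`,
#'   `nRegions`, `regionAreas`.
#' @examples
#' img <- matrix(10L, 20, 20); img[3:7, 3:7] <- 200L
#' otsuFluorescenceArea(img)$totalAreaPx # 25
#' @export
otsuFluorescenceArea <- function(image, bitDepth = NULL) {
  if (length(dim(image)) == 3L) stop("expected a single-channel image")
  image <- as.matrix(image)
  if (diff(range(image)) == 0)
    stop("constant image: the Otsu threshold is undefined")
  mv <- .maxVal(image, bitDepth)
  threshold <- .otsuThreshold(image, mv)
  mask <- image > threshold
  lab <- .label8(mask)
  n <- max(lab)
  areas <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  list(threshold = threshold, mask = mask,
       totalAreaPx = sum(areas), nRegions = n, regionAreas = areas)
}

#' Read / write single-channel images
#'
#' Thin wrappers over EBImage file I/O keeping the package's native-unit
#' matrix convention (integer gray values, not `[0, 1]`).
#'
#' @param path image file (PNG or TIFF).
#' @param bitDepth 8 or 16 (write: output depth).
#' @return `readImageMatrix` returns an integer matrix; `writeImageMatrix`
#'   returns `path` invisibly.
#' @export
readImageMatrix <- function(path, bitDepth = 8) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 3L)
    img <- toGrayscale(aperm(as.array(img), c(2L, 1L, 3L)))
  else
    img <- t(as.matrix(img))
  mv <- 2^bitDepth - 1
  matrix(as.integer(round(img * mv)), nrow(img), ncol(img))
}

#' @rdname readImageMatrix
#' @param image integer matrix in native units.
#' @export
writeImageMatrix <- function(image, path, bitDepth = 8) {
  mv <- 2^bitDepth - 1
  EBImage::writeImage(
    EBImage::Image(t(image / mv)), path,
    bits.per.sample = if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      as.integer(bitDepth) else 8L
  )
  invisible(path)
}
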