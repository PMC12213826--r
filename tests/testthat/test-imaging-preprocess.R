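test_that("pixel sizes reproduce the published device geometries", {
  expect_equal(round(computePixelSize(291, 904), 3), 0.322)
  expect_equal(round(computePixelSize(85, 448), 2), 0.19)
  expect_equal(computePixelSize(100, 100), 1)
  expect_error(computePixelSize(-1, 10), "positive")
})

test_that("the magnification scale factor matches the published 0.59", {
  nano <- computePixelSize(85, 448)
  lion <- computePixelSize(291, 904)
  expect_equal(round(scaleFactor(nano, lion), 2), 0.59)
  expect_equal(scaleFactor(0.322, 0.322), 1)
  expect_equal(scaleFactor(0.644, 0.322), 2)
  # reciprocity
  expect_equal(scaleFactor(nano, lion) * scaleFactor(lion, nano), 1,
               tolerance = 1e-12)
})

test_that("pixel geometry warns about anisotropy beyond 1%", {
  expect_warning(pixelGeometry(c(100, 110), c(100, 100)), "anisotropic")
  expect_silent(g <- pixelGeometry(c(291, 394), c(904, 1224)))
  expect_equal(g$umPerPxMean, mean(c(291 / 904, 394 / 1224)))
})

test_that("rescaling honours dimensions, identity and constants", {
  img <- matrix(runif(448 * 448, 0, 255), 448, 448)
  out <- rescaleImage(img, 0.59)
  expect_equal(dim(out), c(264, 264)) # round(448 * 0.59)
  expect_identical(rescaleImage(img, 1), img)
  const <- rescaleImage(matrix(7, 30, 30), 0.5)
  expect_true(all(abs(const - 7) < 1e-9))
  expect_error(rescaleImage(matrix(0, 10, 10), 0.01), "below 1 pixel")
  # rescaling recovers the destination pixel size within one part in the
  # rounded dimension: 85 um over round(448 * 0.59) px ~ the 20x pixel size
  f <- scaleFactor(computePixelSize(85, 448), computePixelSize(291, 904))
  newDim <- ncol(rescaleImage(matrix(0, 448, 448), f))
  expect_equal(85 / newDim, computePixelSize(291, 904),
               tolerance = 1 / newDim)
})

test_that("CLAHE preserves shape, handles constants, expands contrast, and
           double application stays inside the frozen band", {
  img <- generateCellImage(syntheticImageConfig(
    imageSize = 128, nCells = 5, seed = 2,
    intensityClasses = c(dim = 120, bright = 220)))$image
  c1 <- claheNormalize(img)
  expect_equal(dim(c1), dim(img))
  expect_true(is.integer(c1))
  expect_gte(diff(range(c1)), diff(range(img)))
  # constant image: nothing to equalize
  const <- matrix(42L, 64, 64)
  expect_identical(claheNormalize(const), const)
  # determinism
  expect_identical(claheNormalize(img), c1)
  # frozen idempotence band measured once on this fixture
  c2 <- claheNormalize(c1)
  expect_lte(mean(abs(c2 - c1)), 18)
  expect_lte(max(abs(c2 - c1)), 75)
  expect_error(claheNormalize(array(0, c(4, 4, 3))), "toGrayscale")
})

test_that("grayscale conversion uses ITU-R 601 luminance weights", {
  white <- array(255, c(2, 2, 3))
  expect_equal(toGrayscale(white), matrix(255, 2, 2))
  red <- array(0, c(2, 2, 3))
  red[, , 1] <- 255
  expect_equal(toGrayscale(red), matrix(0.299 * 255, 2, 2))
  gray3 <- array(rep(matrix(1:4, 2), 3), c(2, 2, 3))
  expect_equal(toGrayscale(gray3), matrix(1:4, 2), tolerance = 1e-12)
  expect_identical(toGrayscale(matrix(5, 3, 3)), matrix(5, 3, 3))
})

test_that("crops are fixed-size, centered, zero-padded with recorded
           fractions", {
  img <- matrix(1, 1000, 1000)
  crops <- cropAroundCenters(img, rbind(c(500, 500), c(1, 1)), 224)
  expect_length(crops, 2)
  expect_true(all(vapply(crops, function(cr)
    all(dim(cr$image) == c(224, 224)), logical(1))))
  expect_equal(crops[[1]]$padFraction, 0)
  # corner center keeps a 112 x 112 region: pad = 1 - 112^2 / 224^2 = 0.75
  expect_equal(crops[[2]]$padFraction, 0.75)
  expect_equal(sum(crops[[2]]$image), 112^2)
  # the center pixel lands at zero-based index size/2
  img2 <- matrix(0, 300, 300)
  img2[150, 160] <- 9
  cr <- cropAroundCenters(img2, cbind(150, 160), 224)[[1]]
  expect_equal(cr$image[113, 113], 9)
  # out-of-bounds center skipped with warning, size > image is all padding
  expect_warning(skipped <- cropAroundCenters(img2, cbind(-5, 10), 224),
                 "outside")
  expect_length(skipped, 0)
  big <- cropAroundCenters(matrix(1, 50, 50), cbind(25, 25), 224)[[1]]
  expect_equal(sum(big$image), 50 * 50)
  expect_equal(big$padFraction, 1 - 2500 / 224^2)
})

test_that("Otsu thresholding equals exhaustive inter-class-variance
           maximization", {
  # perfect bimodal image: mask is exactly the bright pixels
  img <- matrix(10L, 20, 20)
  img[3:7, 3:7] <- 200L
  o <- otsuFluorescenceArea(img)
  expect_equal(o$mask, img == 200L)
  expect_equal(o$totalAreaPx, 25)
  expect_equal(o$nRegions, 1)
  # two disjoint squares
  img[12:16, 12:16] <- 200L
  o2 <- otsuFluorescenceArea(img)
  expect_equal(o2$totalAreaPx, 50)
  expect_equal(o2$nRegions, 2)
  # oracle equivalence on random 8-bit images (ties judged by criterion)
  set.seed(9)
  for (i in 1:25) {
    m <- matrix(sample(0:255, 900, replace = TRUE,
                       prob = runif(256)^2), 30, 30)
    got <- otsuFluorescenceArea(m)$threshold
    oracle <- bruteOtsu(as.vector(m))
    expect_equal(otsuCriterion(as.vector(m), got), oracle$criterion,
                 tolerance = 1e-12)
  }
  expect_error(otsuFluorescenceArea(matrix(3L, 5, 5)), "constant")
})

test_that("connected components are 8-connected", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 255L
  m[3, 3] <- 255L # diagonal touch -> one region
  m[6, 6] <- 255L
  o <- otsuFluorescenceArea(m)
  expect_equal(o$nRegions, 2)
  expect_equal(sort(o$regionAreas), c(1, 2))
})

test_that("image matrix I/O round-trips through PNG", {
  img <- generateCellImage(syntheticImageConfig(imageSize = 64, nCells = 3,
                                                seed = 5))$image
  f <- withr::local_tempfile(fileext = ".png")
  writeImageMatrix(img, f)
  back <- readImageMatrix(f)
  expect_identical(back, img)
})
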