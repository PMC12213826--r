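#' Configuration for the synthetic multi-encoder embedding generator
#'
#' Describes a mixture of Gaussian class clusters observed through several
#' "encoder" blocks of differing dimensionality. Informative blocks place the
#' class means at scaled vertices of a simplex (coordinate axes), so every
#' pair of classes is separated by `classSeparation` within-class standard
#' deviations; non-informative blocks are pure noise, identically distributed
#' across classes. This emulates the statistical regime the classifier
#' assumes: several frozen encoders, some carrying class signal, strong class
#' imbalance, and an optional affine domain shift standing in for a second
#' microscope.
#'
#' @slot classNames character, class labels.
#' @slot perClassCounts integer, samples per class (all >= 1).
#' @slot blockDims named integer, encoder id -> feature dimensionality.
#' @slot informativeBlocks character, subset of encoder ids carrying signal.
#' @slot classSeparation non-negative scalar: distance between class means in
#'   units of the within-class standard deviation, per informative block.
#' @slot noiseScale positive scalar, within-class standard deviation.
#' @slot shiftMagnitude non-negative scalar, default magnitude for
#'   [applyDomainShift()].
#' @slot seed integer; fully determines the generated data.
#'
#' @seealso [syntheticEmbeddingConfig()], [generateEmbeddingSet()]
#' @export
setClass("SyntheticEmbeddingConfig",
  representation(
    classNames = "character", perClassCounts = "integer",
    blockDims = "integer", informativeBlocks = "character",
    classSeparation = "numeric", noiseScale = "numeric",
    shiftMagnitude = "numeric", seed = "integer"
  )
)

setValidity("SyntheticEmbeddingConfig", function(object) {
  msg <- character()
  C <- length(object@classNames)
  if (C < 1L || anyDuplicated(object@classNames))
    msg <- c(msg, "classNames must be non-empty and unique")
  if (length(object@perClassCounts) != C || any(object@perClassCounts < 1L))
    msg <- c(msg, "perClassCounts must have one count >= 1 per class")
  if (is.null(names(object@blockDims)) || any(object@blockDims < 1L))
    msg <- c(msg, "blockDims must be a named vector of positive dims")
  if (!all(object@informativeBlocks %in% names(object@blockDims)))
    msg <- c(msg, "informativeBlocks must be a subset of blockDims names")
  if (any(object@blockDims[object@informativeBlocks] < C))
    msg <- c(msg, "informative blocks need dim >= number of classes ",
             "(class means sit on the first C coordinate axes)")
  if (object@classSeparation < 0)
    msg <- c(msg, "classSeparation must be non-negative")
  if (object@noiseScale <= 0) msg <- c(msg, "noiseScale must be positive")
  if (object@shiftMagnitude < 0)
    msg <- c(msg, "shiftMagnitude must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticEmbeddingConfig-class
#' @param classNames,perClassCounts,blockDims,informativeBlocks,classSeparation,noiseScale,shiftMagnitude,seed
#'   see the class slots.
#' @return A validated `SyntheticEmbeddingConfig`.
#' @examples
#' cfg <- syntheticEmbeddingConfig(
#'   classNames = c("living", "necrotic", "dead", "apoptotic"),
#'   perClassCounts = c(461, 137, 73, 71),
#'   blockDims = c(encA = 16, encB = 8),
#'   informativeBlocks = "encA",
#'   classSeparation = 6, seed = 7
#' )
#' @export
syntheticEmbeddingConfig <- function(classNames, perClassCounts, blockDims,
                                     informativeBlocks = names(blockDims),
                                     classSeparation = 4, noiseScale = 1,
                                     shiftMagnitude = 0, seed = 1L) {
  new("SyntheticEmbeddingConfig",
    classNames = as.character(classNames),
    perClassCounts = as.integer(perClassCounts),
    blockDims = setNames(as.integer(blockDims), names(blockDims)),
    informativeBlocks = as.character(informativeBlocks),
    classSeparation = as.numeric(classSeparation),
    noiseScale = as.numeric(noiseScale),
    shiftMagnitude = as.numeric(shiftMagnitude),
    seed = as.integer(seed)
  )
}

# Largest-remainder allocation of class counts to splits so that both the
# per-class row sums and the global split totals (themselves a largest-
# remainder rounding of N * fractions) are met exactly.
allocateSplits <- function(classCounts, fractions) {
  C <- length(classCounts)
  S <- length(fractions)
  N <- sum(classCounts)
  tq <- N * fractions
  targets <- floor(tq)
  short <- as.integer(round(N - sum(targets)))
  if (short > 0L) {
    ord <- order(tq - targets, decreasing = TRUE)
    targets[ord[seq_len(short)]] <- targets[ord[seq_len(short)]] + 1
  }
  A <- outer(classCounts, fractions)
  alloc <- floor(A)
  rowRem <- classCounts - rowSums(alloc)
  colDef <- targets - colSums(alloc)
  rem <- A - alloc
  for (idx in order(rem, decreasing = TRUE)) {
    if (sum(rowRem) == 0) break
    cc <- (idx - 1L) %% C + 1L
    ss <- (idx - 1L) %/% C + 1L
    if (rowRem[cc] > 0 && colDef[ss] > 0) {
      alloc[cc, ss] <- alloc[cc, ss] + 1
      rowRem[cc] <- rowRem[cc] - 1
      colDef[ss] <- colDef[ss] - 1
    }
  }
  while (sum(rowRem) > 0) {
    cc <- which(rowRem > 0)[1L]
    ss <- which(colDef > 0)[1L]
    alloc[cc, ss] <- alloc[cc, ss] + 1
    rowRem[cc] <- rowRem[cc] - 1
    colDef[ss] <- colDef[ss] - 1
  }
  storage.mode(alloc) <- "integer"
  alloc
}

#' Generate a synthetic multi-encoder embedding set with stratified splits
#'
#' Draws every class from an isotropic Gaussian per informative block, class
#' means at `classSeparation * noiseScale / sqrt(2)` times the first C
#' coordinate axes (so all pairwise mean distances equal
#' `classSeparation * noiseScale`); non-informative blocks are identical
#' noise for every class. Rows are shuffled, then split train/val/test with
#' per-class largest-remainder stratification whose split totals equal the
#' rounded global fractions.
#'
#' @param config a [SyntheticEmbeddingConfig-class].
#' @param splitFractions three non-negative numbers summing to 1
#'   (train, val, test); default the 90/9/1 regime.
#' @param requireAllClasses if `TRUE`, error when any split with a positive
#'   fraction receives zero samples of some class.
#' @return An [EmbeddingSet-class] with split tags.
#' @examples
#' cfg <- syntheticEmbeddingConfig("a", 10, c(e = 4), classSeparation = 0)
#' es <- generateEmbeddingSet(cfg)
#' table(splitTags(es))
#' @export
generateEmbeddingSet <- function(config,
                                 splitFractions = c(train = 0.9, val = 0.09,
                                                    test = 0.01),
                                 requireAllClasses = FALSE) {
  stopifnot(is(config, "SyntheticEmbeddingConfig"))
  validObject(config)
  if (length(splitFractions) != 3L || any(splitFractions < 0) ||
      abs(sum(splitFractions) - 1) > 1e-9)
    stop("splitFractions must be three non-negative numbers summing to 1")
  splitNames <- c("train", "val", "test")
  C <- length(config@classNames)
  counts <- config@perClassCounts
  N <- sum(counts)
  sep <- config@classSeparation * config@noiseScale / sqrt(2)

  set.seed(config@seed)
  blocks <- list()
  for (id in names(config@blockDims)) {
    d <- config@blockDims[[id]]
    m <- matrix(rnorm(N * d, sd = config@noiseScale), N, d)
    if (id %in% config@informativeBlocks) {
      row0 <- 0L
      for (ci in seq_len(C)) {
        rows <- row0 + seq_len(counts[ci])
        m[rows, ci] <- m[rows, ci] + sep
        row0 <- row0 + counts[ci]
      }
    }
    blocks[[id]] <- m
  }
  labels <- rep(config@classNames, counts)

  alloc <- allocateSplits(counts, splitFractions)
  if (requireAllClasses &&
      any(alloc[, splitFractions > 0, drop = FALSE] == 0L))
    stop("stratification requested but some split would receive zero ",
         "samples of a class; increase counts or fractions")
  split <- character(N)
  row0 <- 0L
  for (ci in seq_len(C)) {
    rows <- sample(row0 + seq_len(counts[ci])) # shuffle within class
    split[rows] <- rep(splitNames, alloc[ci, ])
    row0 <- row0 + counts[ci]
  }
  perm <- sample.int(N)
  EmbeddingSet(
    blocks = lapply(blocks, function(m) m[perm, , drop = FALSE]),
    labels = labels[perm],
    rowIds = sprintf("cell%05d", seq_len(N)),
    split = split[perm]
  )
}

#' Apply an affine domain shift emulating a second imaging device
#'
#' Adds a fixed random per-dimension offset and gain to every row of every
#' block: `x' = gain_d * x + offset_d` with
#' `gain_d = exp(shiftMagnitude * 0.1 * g_d)` and
#' `offset_d = shiftMagnitude * sd_d * z_d`, where `g_d, z_d ~ N(0, 1)` and
#' `sd_d` is the empirical standard deviation of that dimension. Labels and
#' class structure are untouched; `shiftMagnitude = 0` is the identity.
#'
#' @param set an [EmbeddingSet-class].
#' @param shiftMagnitude non-negative scalar.
#' @param seed integer seed for the shift draws.
#' @return The shifted `EmbeddingSet`.
#' @export
applyDomainShift <- function(set, shiftMagnitude, seed = 1L) {
  stopifnot(is(set, "EmbeddingSet"))
  if (shiftMagnitude < 0) stop("shiftMagnitude must be non-negative")
  if (shiftMagnitude == 0) return(set)
  set.seed(as.integer(seed))
  blocks <- lapply(set@blocks, function(m) {
    d <- ncol(m)
    sds <- apply(m, 2L, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1
    gain <- exp(shiftMagnitude * 0.1 * rnorm(d))
    offset <- shiftMagnitude * sds * rnorm(d)
    sweep(sweep(m, 2L, gain, "*"), 2L, offset, "+")
  })
  new("EmbeddingSet",
    blocks = blocks, labels = set@labels, rowIds = set@rowIds,
    split = set@split
  )
}

#' Configuration for the synthetic microscopy image generator
#'
#' @slot imageSize integer, square image side in pixels.
#' @slot nCells integer, number of disks to place.
#' @slot cellRadiusRange numeric length-2, min/max disk radius in pixels.
#' @slot intensityClasses named numeric, label -> mean intensity (native
#'   units of the chosen bit depth).
#' @slot bitDepth 8 or 16.
#' @slot backgroundLevel numeric, background intensity (native units).
#' @slot noiseSd numeric, additive Gaussian noise standard deviation.
#' @slot seed integer.
#'
#' @seealso [syntheticImageConfig()], [generateCellImage()]
#' @export
setClass("SyntheticImageConfig",
  representation(
    imageSize = "integer", nCells = "integer", cellRadiusRange = "numeric",
    intensityClasses = "numeric", bitDepth = "integer",
    backgroundLevel = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("SyntheticImageConfig", function(object) {
  msg <- character()
  if (object@imageSize < 8L) msg <- c(msg, "imageSize must be >= 8")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (length(object@cellRadiusRange) != 2L ||
      any(object@cellRadiusRange <= 0) ||
      diff(object@cellRadiusRange) < 0)
    msg <- c(msg, "cellRadiusRange must be increasing and positive")
  if (max(object@cellRadiusRange) * 2 >= object@imageSize)
    msg <- c(msg, "cells must fit inside the image")
  if (length(object@intensityClasses) == 0L ||
      is.null(names(object@intensityClasses)))
    msg <- c(msg, "intensityClasses must be a named numeric vector")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticImageConfig-class
#' @param imageSize,nCells,cellRadiusRange,intensityClasses,bitDepth,backgroundLevel,noiseSd,seed
#'   see the class slots.
#' @export
syntheticImageConfig <- function(imageSize = 256, nCells = 10,
                                 cellRadiusRange = c(6, 12),
                                 intensityClasses = c(bright = 200),
                                 bitDepth = 8, backgroundLevel = 20,
                                 noiseSd = 3, seed = 1L) {
  new("SyntheticImageConfig",
    imageSize = as.integer(imageSize), nCells = as.integer(nCells),
    cellRadiusRange = as.numeric(cellRadiusRange),
    intensityClasses = intensityClasses, bitDepth = as.integer(bitDepth),
    backgroundLevel = as.numeric(backgroundLevel),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed)
  )
}

#' Render a synthetic microscopy frame of bright disks on a dark background
#'
#' Places non-overlapping anti-aliased disks (edge coverage linear over one
#' pixel) of per-class mean intensity on a darker background, adds Gaussian
#' noise, clips to the bit depth, and returns the image together with one
#' binary mask, label and center per cell.
#'
#' @param config a [SyntheticImageConfig-class].
#' @param maxTries placement retry budget per cell before erroring.
#' @return A list with `image` (integer matrix), `masks` (list of logical
#'   matrices), `labels` (character), `centers` (n x 2 matrix, row/col), and
#'   `noiseless` (the image before noise, for thresholding oracles).
#' @examples
#' img <- generateCellImage(syntheticImageConfig(nCells = 3, seed = 2))
#' length(img$masks)
#' @export
generateCellImage <- function(config, maxTries = 1000L) {
  stopifnot(is(config, "SyntheticImageConfig"))
  validObject(config)
  set.seed(config@seed)
  sz <- config@imageSize
  maxVal <- 2^config@bitDepth - 1
  canvas <- matrix(config@backgroundLevel, sz, sz)
  masks <- list()
  labs <- character(0)
  centers <- matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("row", "col")))
  placedR <- numeric(0)
  rowIdx <- matrix(seq_len(sz), sz, sz)
  colIdx <- t(rowIdx)
  for (i in seq_len(config@nCells)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      r <- runif(1, config@cellRadiusRange[1], config@cellRadiusRange[2])
      cy <- runif(1, r + 1, sz - r)
      cx <- runif(1, r + 1, sz - r)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
              placedR + r + 1)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place cell ", i, " within the retry budget; ",
           "reduce nCells or cell radius")
    lab <- sample(names(config@intensityClasses), 1L)
    intensity <- config@intensityClasses[[lab]]
    distm <- sqrt((rowIdx - cy)^2 + (colIdx - cx)^2)
    coverage <- pmin(1, pmax(0, r + 0.5 - distm))
    canvas <- canvas + coverage * (intensity - config@backgroundLevel)
    masks[[i]] <- distm <= r
    labs <- c(labs, lab)
    centers <- rbind(centers, c(cy, cx))
    placedR <- c(placedR, r)
  }
  noiseless <- matrix(as.integer(pmin(maxVal, pmax(0, round(canvas)))), sz, sz)
  noisy <- canvas + rnorm(sz * sz, sd = config@noiseSd)
  image <- matrix(as.integer(pmin(maxVal, pmax(0, round(noisy)))), sz, sz)
  list(image = image, masks = masks, labels = labs, centers = centers,
       noiseless = noiseless)
}
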