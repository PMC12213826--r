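test_that("split fractions produce the expected stratified row counts", {
  cfg <- syntheticEmbeddingConfig(c("a", "b"), c(50, 50), c(e = 4),
                                  classSeparation = 2, seed = 1)
  es <- generateEmbeddingSet(cfg, c(0.9, 0.09, 0.01))
  tab <- table(splitTags(es))
  expect_equal(as.integer(tab[c("train", "val", "test")]), c(90L, 9L, 1L))
  trainLabs <- labels(es)[splitTags(es) == "train"]
  expect_setequal(as.character(unique(trainLabs)), c("a", "b"))
})

test_that("every split contains every class when fractions x counts >= 1", {
  cfg <- syntheticEmbeddingConfig(c("a", "b", "c"), c(100, 80, 60),
                                  c(e = 4), seed = 3)
  es <- generateEmbeddingSet(cfg, c(0.6, 0.3, 0.1))
  tab <- table(labels(es), splitTags(es))
  expect_true(all(tab > 0))
})

test_that("strict stratification errors when a split would miss a class", {
  cfg <- syntheticEmbeddingConfig(c("a", "b"), c(50, 50), c(e = 4), seed = 1)
  expect_error(
    generateEmbeddingSet(cfg, c(0.9, 0.09, 0.01), requireAllClasses = TRUE),
    "zero samples"
  )
})

test_that("identical config and seed give bit-identical embedding sets", {
  cfg <- syntheticEmbeddingConfig(c("a", "b"), c(30, 20),
                                  c(x = 5, y = 3), informativeBlocks = "x",
                                  classSeparation = 3, seed = 42)
  e1 <- generateEmbeddingSet(cfg)
  e2 <- generateEmbeddingSet(cfg)
  expect_identical(blockMatrix(e1, "x"), blockMatrix(e2, "x"))
  expect_identical(blockMatrix(e1, "y"), blockMatrix(e2, "y"))
  expect_identical(labels(e1), labels(e2))
  expect_identical(splitTags(e1), splitTags(e2))
})

test_that("informative blocks separate class means, noise blocks do not", {
  cfg <- syntheticEmbeddingConfig(c("a", "b"), c(200, 200),
                                  c(sig = 4, noise = 4),
                                  informativeBlocks = "sig",
                                  classSeparation = 6, seed = 7)
  es <- generateEmbeddingSet(cfg, c(1, 0, 0))
  sig <- blockMatrix(es, "sig")
  noi <- blockMatrix(es, "noise")
  la <- labels(es) == "a"
  dSig <- sqrt(sum((colMeans(sig[la, ]) - colMeans(sig[!la, ]))^2))
  dNoi <- sqrt(sum((colMeans(noi[la, ]) - colMeans(noi[!la, ]))^2))
  expect_equal(dSig, 6, tolerance = 0.1)
  expect_lt(dNoi, 1)
})

test_that("zero class separation keeps the classifier at chance level", {
  cfg <- syntheticEmbeddingConfig(c("a", "b", "c", "d"), rep(300, 4),
                                  c(e = 8), classSeparation = 0, seed = 11)
  es <- generateEmbeddingSet(cfg, c(0.5, 0.42, 0.08))
  idx <- buildIndex(es, config = searchConfig(kMin = 5, kMax = 40))
  val <- splitSet(es, "val")
  acc <- macroAccuracy(labels(val),
                       adaptivePredict(idx, val)$predicted_label)
  # chance = 25%; 3 sigma of the per-class binomial (~126 queries/class,
  # averaged over 4 classes) is ~5.8 points
  expect_lt(acc, 25 + 3 * sqrt(0.25 * 0.75 / 126) / sqrt(4) * 100)
})

test_that("domain shift of magnitude zero is the identity", {
  es <- makeToySet(seed = 2)
  shifted <- applyDomainShift(es, 0, seed = 9)
  expect_identical(blockMatrix(shifted, "sig"), blockMatrix(es, "sig"))
})

test_that("small domain shift barely moves transfer accuracy, large shift
           collapses it toward chance", {
  cfg <- syntheticEmbeddingConfig(c("a", "b", "c"), rep(200, 3), c(e = 16),
                                  classSeparation = 6, seed = 5)
  es <- generateEmbeddingSet(cfg, c(0.8, 0.19, 0.01))
  tr <- splitSet(es, "train")
  va <- splitSet(es, "val")
  idx <- buildIndex(tr, config = searchConfig(kMin = 3, kMax = 30),
                    useTrainSplit = FALSE)
  accAt <- function(m) {
    vs <- applyDomainShift(va, m, seed = 77)
    macroAccuracy(labels(vs), adaptivePredict(idx, vs)$predicted_label)
  }
  inDomain <- accAt(0)
  expect_gt(accAt(0.3), inDomain - 5)
  expect_lt(accAt(10), 55) # 3-class chance is 33%
  expect_identical(labels(applyDomainShift(va, 10, 1)), labels(va))
})

test_that("cell image generator honours counts, bounds and determinism", {
  cfg <- syntheticImageConfig(imageSize = 96, nCells = 5, seed = 4)
  out <- generateCellImage(cfg)
  expect_length(out$masks, 5)
  expect_length(out$labels, 5)
  expect_true(all(out$centers >= 1 & out$centers <= 96))
  expect_true(all(vapply(out$masks, sum, numeric(1)) > 0))
  out2 <- generateCellImage(cfg)
  expect_identical(out$image, out2$image)

  empty <- generateCellImage(syntheticImageConfig(imageSize = 64,
                                                  nCells = 0, seed = 1))
  expect_length(empty$masks, 0)
  expect_true(all(empty$image >= 0))
})

test_that("impossible packing exhausts the retry budget with an error", {
  cfg <- syntheticImageConfig(imageSize = 64, nCells = 50,
                              cellRadiusRange = c(10, 12), seed = 1)
  expect_error(generateCellImage(cfg, maxTries = 50), "retry budget")
})

test_that("two intensity classes are separated by Otsu on the noiseless
           render", {
  cfg <- syntheticImageConfig(imageSize = 128, nCells = 6, seed = 8,
                              intensityClasses = c(dim = 45, bright = 220),
                              noiseSd = 0)
  out <- generateCellImage(cfg)
  o <- otsuFluorescenceArea(out$noiseless)
  bright <- out$labels == "bright"
  expect_true(any(bright) && !all(bright)) # this seed draws both classes
  brightMask <- Reduce(`|`, out$masks[bright])
  dimMask <- Reduce(`|`, out$masks[!bright])
  # cores of bright cells are above threshold, dim cores below
  expect_true(mean(out$noiseless[brightMask] > o$threshold) > 0.9)
  expect_true(mean(out$noiseless[dimMask] > o$threshold) < 0.1)
})
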