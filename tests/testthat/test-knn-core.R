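test_that("class weights follow the inverse-frequency rule and conserve N", {
  # balanced case: all weights 1
  expect_equal(unname(computeClassWeights(rep(c("a", "b"), each = 10))),
               c(1, 1))
  # 90/10 imbalance: w = N / (C * N_i)
  w <- computeClassWeights(rep(c("a", "b"), c(90, 10)))
  expect_equal(unname(w), c(100 / 180, 100 / 20), tolerance = 1e-12)
  # conservation sum(w_i * N_i) = N on random databases
  set.seed(1)
  for (i in 1:10) {
    C <- sample(2:6, 1)
    counts <- sample(1:50, C, replace = TRUE)
    labs <- rep(letters[1:C], counts)
    w <- computeClassWeights(labs)
    expect_equal(sum(w * counts), sum(counts), tolerance = 1e-9)
  }
  # reweighting off: all ones
  expect_true(all(computeClassWeights(rep(c("a", "b"), c(90, 10)),
                                      reweight = FALSE) == 1))
  expect_error(computeClassWeights(character(0)), "empty")
})

test_that("normalized entropy matches hand-evaluated cases and bounds", {
  expect_equal(normalizedEntropy(c("A", "A", "A", "A")), 0)
  expect_equal(normalizedEntropy(c("A", "B", "C", "D")), 1)
  expect_equal(normalizedEntropy(c("A", "A", "A", "B")), 0.4056391,
               tolerance = 1e-6)
  expect_equal(normalizedEntropy(c("A", "A", "B", "C")), 0.75,
               tolerance = 1e-12)
  expect_error(normalizedEntropy("A"), "k >= 2")
  # H in [0,1]; 0 iff pure, 1 iff all distinct — random multisets
  set.seed(2)
  for (i in 1:50) {
    k <- sample(2:9, 1)
    labs <- sample(letters[1:4], k, replace = TRUE)
    h <- normalizedEntropy(labs)
    expect_gte(h, 0)
    expect_lte(h, 1)
    if (length(unique(labs)) == 1L) expect_equal(h, 0)
    if (length(unique(labs)) == k) expect_equal(h, 1)
    if (length(unique(labs)) > 1L && length(unique(labs)) < k) {
      expect_gt(h, 0)
      expect_lt(h, 1)
    }
  }
})

test_that("certainty is the strictly decreasing complement of entropy", {
  expect_equal(certainty(0), 100)
  expect_equal(certainty(1), 0)
  expect_equal(certainty(0.4056391), 59.43609, tolerance = 1e-5)
  e <- seq(0, 1, by = 0.05)
  expect_true(all(diff(certainty(e)) < 0))
  expect_error(certainty(1.2), "\\[0, 1\\]")
})

test_that("weighted vote follows Eq.-style weighting and sane tie-breaks", {
  # unanimous
  expect_equal(weightedVote(c("A", "A", "A"), c(A = 0.2, B = 9)), "A")
  # minority class wins through its weight: scores 1.667 vs 5.0
  expect_equal(weightedVote(c("A", "A", "A", "B"),
                            c(A = 100 / 180, B = 5)), "B")
  expect_error(weightedVote(c("A", "Z"), c(A = 1)), "no class weight")
  # tie broken by smaller summed distance, then lexicographically
  expect_equal(weightedVote(c("A", "B"), c(A = 1, B = 1),
                            distances = c(2, 1)), "B")
  expect_equal(weightedVote(c("B", "A"), c(A = 1, B = 1)), "A")
})

test_that("equal weights reduce the weighted vote to plurality on every
           multiset up to k = 7 with 3 classes", {
  w <- c(a = 1, b = 1, c = 1)
  for (k in c(1, 3, 5, 7)) {
    grids <- do.call(expand.grid,
                     rep(list(c("a", "b", "c")), k))
    for (i in seq_len(nrow(grids))) {
      labs <- as.character(unlist(grids[i, ]))
      expect_identical(weightedVote(labs, w), pluralityVote(labs))
    }
  }
})

test_that("macro metrics match the hand-computed confusion matrix", {
  # confusion [[9,1],[2,3]]: recalls 0.9, 0.6; precisions 9/11, 3/4
  yTrue <- rep(c("A", "B"), c(10, 5))
  yPred <- c(rep("A", 9), "B", rep("A", 2), rep("B", 3))
  expect_equal(macroAccuracy(yTrue, yPred), 75)
  expect_equal(macroPrecision(yTrue, yPred), (9 / 11 + 3 / 4) / 2 * 100,
               tolerance = 1e-9)
  expect_equal(macroAccuracy(yTrue, yTrue), 100)
  expect_equal(macroPrecision(yTrue, yTrue), 100)
  expect_warning(p <- macroPrecision(c("A", "B"), c("A", "A")),
                 "never predicted")
  expect_equal(p, 25) # precision A = 1/2, B = 0
  expect_error(macroAccuracy(character(0), character(0)), "empty")
})

test_that("adaptive search stops immediately in a pure cluster", {
  set.seed(3)
  X <- rbind(matrix(rnorm(200, 10, 0.1), 50), matrix(rnorm(200, -10, 0.1), 50))
  idx <- buildIndex(X, labels = rep(c("A", "B"), each = 50),
                    config = searchConfig(kMin = 3, kMax = 48,
                                          entropyThreshold = 0.3))
  p <- adaptivePredict(idx, matrix(10, 1, 4))
  expect_equal(p$k_used, 3L)
  expect_equal(p$entropy, 0)
  expect_equal(p$certainty_percent, 100)
  expect_equal(p$predicted_label, "A")
})

test_that("an equidistant query walks the full doubling schedule to kMax", {
  # deterministic interleaved radii: neighbour labels alternate A,B,A,B...
  rA <- 1 + 0.02 * (0:19)
  rB <- 1.01 + 0.02 * (0:19)
  X <- cbind(c(rA, -rB), 0)
  idx <- buildIndex(X, labels = rep(c("A", "B"), each = 20),
                    config = searchConfig(kMin = 3, kMax = 12,
                                          entropyThreshold = 0.1))
  p <- adaptivePredict(idx, matrix(0, 1, 2), returnNeighbors = TRUE)
  expect_equal(p$k_used, 12L)
  # a 6/6 two-class neighbourhood at k = 12 has H = ln(2) / ln(12),
  # well above the 0.1 threshold at every visited k (3 -> 6 -> 12)
  expect_equal(p$entropy, log(2) / log(12), tolerance = 1e-12)
  nb <- attr(p, "neighbors")[[1]]
  expect_equal(nb$labels, rep(c("A", "B"), 6))
})

test_that("the doubling schedule visits the expected k values", {
  expect_equal(entroKNN:::.kSchedule(3L, 1000L, 2),
               c(3L, 6L, 12L, 24L, 48L, 96L, 192L, 384L, 768L, 1000L))
  expect_equal(entroKNN:::.kSchedule(5L, 5L, 2), 5L)
})

test_that("kMax beyond the database size is clamped with a warning", {
  X <- matrix(rnorm(40), 20, 2)
  idx <- buildIndex(X, labels = rep(c("A", "B"), 10),
                    config = searchConfig(kMin = 3, kMax = 100,
                                          entropyThreshold = 0))
  expect_warning(p <- adaptivePredict(idx, matrix(0, 1, 2)), "clamped")
  expect_lte(p$k_used, 20L)
})

test_that("k_used stays within bounds and neighbour distances are sorted", {
  es <- makeToySet(seed = 9, separation = 2,
                   counts = c(80, 40, 30))
  idx <- buildIndex(es, config = searchConfig(kMin = 3, kMax = 24,
                                              entropyThreshold = 0.2))
  val <- splitSet(es, "val")
  p <- adaptivePredict(idx, val, returnNeighbors = TRUE)
  expect_true(all(p$k_used >= 3 & p$k_used <= 24))
  for (nb in attr(p, "neighbors"))
    expect_true(all(diff(nb$distances) >= 0))
  expect_equal(p$certainty_percent, (1 - p$entropy) * 100)
})

test_that("entropy for stopping uses raw counts, not reweighted ones", {
  # heavily weighted minority: vote flips, entropy must not
  labs <- c(rep("maj", 9), "min")
  w <- computeClassWeights(rep(c("maj", "min"), c(950, 50)))
  expect_equal(weightedVote(labs, w), "min") # 9 * 0.526 < 1 * 10
  expect_equal(normalizedEntropy(labs),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(10),
               tolerance = 1e-12)
})

test_that("index save / load round trip preserves predictions", {
  es <- makeToySet(seed = 12)
  idx <- buildIndex(es, config = searchConfig(kMin = 3, kMax = 12))
  val <- splitSet(es, "val")
  p1 <- adaptivePredict(idx, val)
  path <- withr::local_tempdir()
  saveIndex(idx, path)
  idx2 <- loadIndex(path)
  p2 <- adaptivePredict(idx2, val)
  expect_identical(p1$predicted_label, p2$predicted_label)
  expect_equal(p1$entropy, p2$entropy)
  expect_identical(idx2@classWeights, idx@classWeights)
})

test_that("degenerate inputs are rejected with explicit errors", {
  expect_error(buildIndex(matrix(numeric(0), 0, 3), labels = character(0)),
               "empty")
  X <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(buildIndex(X, labels = c("a", "b")), "finite")
  es <- makeToySet(seed = 1)
  idx <- buildIndex(es, config = searchConfig(kMin = 2, kMax = 5))
  expect_error(searchNeighbors(idx, matrix(0, 1, 3), 2),
               "dimensionality")
})
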