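# Independent oracles used across tests: explicit-loop brute force
# implementations kept deliberately separate from the package's code paths.

# k nearest rows of X to a single query, plain R, explicit distance loops.
bruteKnn <- function(X, q, k, metric = c("L2", "Canberra")) {
  metric <- match.arg(metric)
  d <- apply(X, 1L, function(r) {
    if (metric == "L2") sqrt(sum((r - q)^2))
    else {
      num <- abs(r - q)
      den <- abs(r) + abs(q)
      sum(ifelse(den > 0, num / den, 0))
    }
  })
  ord <- order(d)[seq_len(k)]
  list(ids = ord, distances = d[ord])
}

# Exhaustive Otsu: per-threshold probability/mean loop.
bruteOtsu <- function(v, levels = 256L) {
  h <- tabulate(as.integer(v) + 1L, nbins = levels)
  p <- h / sum(h)
  best <- -1
  bt <- 0L
  for (t in 0:(levels - 2L)) {
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    mu1 <- sum(((t + 1):(levels - 1)) * p[(t + 2):levels]) / w1
    v2 <- w0 * w1 * (mu0 - mu1)^2
    if (v2 > best) {
      best <- v2
      bt <- t
    }
  }
  list(threshold = bt, criterion = best)
}

# Between-class variance of a given integer threshold (for tie-tolerant
# equivalence checks).
otsuCriterion <- function(v, t, levels = 256L) {
  p <- tabulate(as.integer(v) + 1L, nbins = levels) / length(v)
  w0 <- sum(p[1:(t + 1)])
  w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(-Inf)
  mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
  mu1 <- sum(((t + 1):(levels - 1)) * p[(t + 2):levels]) / w1
  w0 * w1 * (mu0 - mu1)^2
}

# Plurality vote with lexicographic tie-break, the unweighted reference.
pluralityVote <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]
}

# Small well-separated embedding set reused by several suites.
makeToySet <- function(seed = 1L, separation = 8, counts = c(60, 60, 60),
                       blocks = c(sig = 8L), informative = "sig",
                       fractions = c(0.7, 0.25, 0.05)) {
  cfg <- syntheticEmbeddingConfig(
    classNames = paste0("cl", seq_along(counts)), perClassCounts = counts,
    blockDims = blocks, informativeBlocks = informative,
    classSeparation = separation, seed = seed
  )
  generateEmbeddingSet(cfg, splitFractions = fractions)
}
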