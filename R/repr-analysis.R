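#' Centered PCA projection with sign-fixed components
#'
#' Standard centered (not scaled) PCA. Each component's sign is fixed by
#' making its largest-magnitude loading positive, so results are
#' deterministic across LAPACK implementations.
#'
#' @param X numeric matrix, n x d.
#' @param nComponents number of components to keep
#'   (`<= min(n, d)`).
#' @return List with `scores` (n x m), `rotation` (d x m),
#'   `explainedVarianceRatios` (full-length ratio vector), `center`.
#' @examples
#' p <- pcaReduce(matrix(rnorm(200), 50), 2)
#' sum(p$explainedVarianceRatios)
#' @export
pcaReduce <- function(X, nComponents) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (nComponents > min(n, d))
    stop("nComponents (", nComponents, ") exceeds min(n, d) = ", min(n, d))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  m <- min(nComponents, ncol(p$rotation))
  rot <- p$rotation[, seq_len(m), drop = FALSE]
  sc <- p$x[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  ratios <- p$sdev^2 / sum(p$sdev^2)
  list(scores = sc, rotation = rot, explainedVarianceRatios = ratios,
       center = p$center)
}

#' Class-by-class mean cosine-similarity matrix after PCA
#'
#' Embeddings are first projected to `pcaDims` principal components (the
#' projection is reduced with a warning when `min(n, d)` is smaller, as on
#' small synthetic fixtures). Cell (a, b) then averages the cosine
#' similarity over all cross-class pairs; diagonal cells average over
#' unordered distinct within-class pairs — self pairs are excluded since
#' they are identically 1 and would inflate intra-class means.
#'
#' @param X numeric matrix (or an [EmbeddingSet-class], concatenated).
#' @param labels class label per row (taken from the set when omitted).
#' @param pcaDims PCA dimensionality (default 100).
#' @return A [ClassSimilarityMatrix-class].
#' @examples
#' X <- rbind(matrix(rnorm(80, 3), 20), matrix(rnorm(80, -3), 20))
#' csm <- classCosineMatrix(X, rep(c("a", "b"), each = 20), pcaDims = 4)
#' similarityMatrix(csm)
#' @export
classCosineMatrix <- function(X, labels = NULL, pcaDims = 100L) {
  if (is(X, "EmbeddingSet")) {
    if (is.null(labels)) labels <- labels(X)
    X <- concatenateBlocks(X)
  }
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X)) stop("labels length must match rows")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs >= 2 samples (within-class similarity is ",
         "undefined for singletons): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  m <- min(pcaDims, nrow(X), ncol(X))
  if (m < pcaDims)
    warning("PCA reduced to ", m, " dims (min(n, d) < ", pcaDims, ")")
  Z <- pcaReduce(X, m)$scores
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) stop("zero-norm row after PCA projection")
  Z <- Z / nrm
  S <- tcrossprod(Z)
  classes <- levels(labels)
  C <- length(classes)
  sim <- matrix(0, C, C, dimnames = list(classes, classes))
  np <- matrix(0, C, C, dimnames = list(classes, classes))
  for (a in seq_len(C)) {
    ia <- which(labels == classes[a])
    for (b in a:C) {
      if (a == b) {
        block <- S[ia, ia, drop = FALSE]
        n <- length(ia)
        sim[a, a] <- (sum(block) - n) / (n * (n - 1)) # exclude self pairs
        np[a, a] <- n * (n - 1) / 2
      } else {
        ib <- which(labels == classes[b])
        block <- S[ia, ib, drop = FALSE]
        sim[a, b] <- sim[b, a] <- mean(block)
        np[a, b] <- np[b, a] <- length(block)
      }
    }
  }
  new("ClassSimilarityMatrix", classes = classes, similarity = sim,
      nPairs = np, pcaDims = as.integer(m))
}

#' @rdname ClassSimilarityMatrix
#' @export
setMethod("similarityMatrix", "ClassSimilarityMatrix",
          function(object) object@similarity)

setMethod("show", "ClassSimilarityMatrix", function(object) {
  cat("ClassSimilarityMatrix over", length(object@classes),
      "classes (PCA to", object@pcaDims, "dims)\n")
  print(round(object@similarity, 3))
})

#' Intra/inter-class similarity and class separability
#'
#' From a class cosine-similarity matrix: `intraClass` is the mean diagonal,
#' `interClass` the mean off-diagonal, and `separability` the average per
#' class of the difference between the diagonal entry and the sum of the
#' off-diagonal entries of that row.
#'
#' @param x a [ClassSimilarityMatrix-class] or a plain symmetric matrix.
#' @return List with `intraClass`, `interClass`, `separability`.
#' @examples
#' separability(diag(3)) # intra 1, inter 0, separability 1
#' @export
separability <- function(x) {
  m <- if (is(x, "ClassSimilarityMatrix")) x@similarity else as.matrix(x)
  C <- nrow(m)
  if (C < 2L) stop("need at least 2 classes")
  off <- m
  diag(off) <- NA
  list(
    intraClass = mean(diag(m)),
    interClass = mean(off, na.rm = TRUE),
    separability = mean(diag(m) - rowSums(off, na.rm = TRUE))
  )
}

.rbfGram <- function(X) {
  D <- as.matrix(dist(X))
  sigma <- median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0)
    stop("zero-variance input: all rows identical, RBF bandwidth undefined")
  exp(-D^2 / (2 * sigma^2))
}

#' RBF centered kernel alignment between two representations
#'
#' `CKA(X, Y) = HSIC(K, L) / sqrt(HSIC(K, K) * HSIC(L, L))` with Gaussian
#' kernels whose bandwidth is the median pairwise Euclidean distance of each
#' input (median heuristic) and the biased HSIC estimator
#' `tr(K H L H) / (n - 1)^2`. The rows of X and Y must describe the same n
#' samples; the value lies in (0, 1], is symmetric, and with the median
#' heuristic is invariant to rotation and isotropic scaling of either input.
#'
#' @param X,Y numeric matrices with the same number of rows (n >= 3).
#' @return Scalar alignment.
#' @examples
#' X <- matrix(rnorm(60), 20)
#' rbfCKA(X, X) # 1
#' @export
rbfCKA <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must describe the same samples (rows)")
  if (n < 3L) stop("need n >= 3 samples")
  K <- .rbfGram(X)
  L <- .rbfGram(Y)
  H <- diag(n) - 1 / n
  KH <- H %*% K %*% H
  LH <- H %*% L %*% H
  hsic <- function(A, B) sum(A * t(B)) / (n - 1)^2
  hsic(KH, LH) / sqrt(hsic(KH, KH) * hsic(LH, LH))
}

#' PCA intrinsic dimensionality
#'
#' The smallest number of principal components whose cumulative explained
#' variance ratio reaches `varianceFraction`.
#'
#' @param X numeric matrix (n >= 2 rows).
#' @param varianceFraction fraction in (0, 1], default 0.95.
#' @return Integer component count.
#' @examples
#' intrinsicDimensionality(cbind(1:10, (1:10) * 2)) # rank-1 -> 1
#' @export
intrinsicDimensionality <- function(X, varianceFraction = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need n >= 2 rows")
  if (varianceFraction <= 0 || varianceFraction > 1)
    stop("varianceFraction must lie in (0, 1]")
  ratios <- pcaReduce(X, 1L)$explainedVarianceRatios
  as.integer(which(cumsum(ratios) >= varianceFraction - 1e-12)[1L])
}

#' Per-encoder loading contributions to the top principal components
#'
#' Projects the concatenated embedding onto its principal components and
#' scores each encoder block by the mean squared loading (energy) of its
#' columns, averaged over the top components and normalized to sum to 1.
#' Squaring avoids sign cancellation across loadings.
#'
#' @param X concatenated matrix with a `"blockLayout"` attribute (as from
#'   [concatenateBlocks()]), or an [EmbeddingSet-class].
#' @param layout named list of zero-based `c(start, end)` column offsets;
#'   taken from `X` when omitted.
#' @param topComponents how many leading components to average over;
#'   default: the intrinsic dimensionality at 95% variance.
#' @return Named numeric scores, non-negative, summing to 1.
#' @examples
#' es <- EmbeddingSet(list(A = matrix(rnorm(40), 10),
#'                         B = matrix(0, 10, 3)), rep("x", 10))
#' blockContributions(es)
#' @export
blockContributions <- function(X, layout = NULL, topComponents = NULL) {
  if (is(X, "EmbeddingSet")) X <- concatenateBlocks(X)
  if (is.null(layout)) layout <- attr(X, "blockLayout")
  if (is.null(layout)) stop("a block layout is required")
  X <- as.matrix(X)
  ends <- vapply(layout, function(b) b[["end"]], numeric(1))
  if (max(ends) != ncol(X))
    stop("layout does not cover all columns of X")
  if (is.null(topComponents))
    topComponents <- intrinsicDimensionality(X)
  m <- min(topComponents, nrow(X), ncol(X))
  rot <- pcaReduce(X, m)$rotation
  scores <- vapply(layout, function(b) {
    cols <- (b[["start"]] + 1L):b[["end"]]
    mean(colMeans(rot[cols, , drop = FALSE]^2))
  }, numeric(1))
  scores / sum(scores)
}
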