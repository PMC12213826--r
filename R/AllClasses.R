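#' Search configuration for the adaptive k-NN classifier
#'
#' Holds the neighbourhood bounds, the entropy stopping threshold, the
#' retrieval metric and the HNSW graph parameters. The adaptive search starts
#' at `kMin` neighbours and multiplies k by `growthFactor` (final step clamped
#' to `kMax`) until the normalized entropy of the neighbour labels drops
#' strictly below `entropyThreshold`.
#'
#' @slot kMin integer, smallest neighbourhood size (>= 2; the entropy
#'   normalizer log(k) vanishes at k = 1).
#' @slot kMax integer, largest neighbourhood size (clamped to the database
#'   size at query time).
#' @slot entropyThreshold numeric in `[0, 1]`.
#' @slot metric `"L2"` or `"Canberra"`.
#' @slot growthFactor numeric > 1, multiplicative k schedule (default 2).
#' @slot hnswM integer, HNSW connectivity parameter M.
#' @slot efConstruction integer, HNSW construction beam width.
#' @slot efSearch integer, HNSW query beam width; `NA` means
#'   `max(2 * k, 128)`, growing with k so recall does not collapse.
#'
#' @seealso [searchConfig()]
#' @export
setClass("SearchConfig",
  representation(
    kMin = "integer", kMax = "integer", entropyThreshold = "numeric",
    metric = "character", growthFactor = "numeric", hnswM = "integer",
    efConstruction = "integer", efSearch = "integer"
  ),
  prototype(
    kMin = 3L, kMax = 1000L, entropyThreshold = 0.3, metric = "L2",
    growthFactor = 2, hnswM = 32L, efConstruction = 200L,
    efSearch = NA_integer_
  )
)

setValidity("SearchConfig", function(object) {
  msg <- character()
  if (length(object@kMin) != 1L || is.na(object@kMin) || object@kMin < 2L)
    msg <- c(msg, "kMin must be a single integer >= 2")
  if (length(object@kMax) != 1L || is.na(object@kMax) ||
      object@kMax < object@kMin)
    msg <- c(msg, "kMax must be a single integer >= kMin")
  if (length(object@entropyThreshold) != 1L ||
      is.na(object@entropyThreshold) || object@entropyThreshold < 0 ||
      object@entropyThreshold > 1)
    msg <- c(msg, "entropyThreshold must lie in [0, 1]")
  if (!object@metric %in% c("L2", "Canberra"))
    msg <- c(msg, "metric must be 'L2' or 'Canberra'")
  if (length(object@growthFactor) != 1L || is.na(object@growthFactor) ||
      object@growthFactor <= 1)
    msg <- c(msg, "growthFactor must be > 1")
  if (object@hnswM < 2L) msg <- c(msg, "hnswM must be >= 2")
  if (object@efConstruction < 1L) msg <- c(msg, "efConstruction must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A set of per-encoder embedding blocks sharing rows
#'
#' One block per image encoder: a numeric matrix with one row per cell image
#' and that encoder's feature dimensionality as columns. All blocks share the
#' same rows (cells) in the same order. Labels, stable row identifiers and an
#' optional train/val/test split tag ride along.
#'
#' @slot blocks named list of numeric matrices, equal row counts.
#' @slot labels factor of class labels, one per row.
#' @slot rowIds character vector of unique row identifiers.
#' @slot split character vector of split tags (`"train"`, `"val"`, `"test"`,
#'   `"transfer"` or `NA`), one per row.
#'
#' @seealso [EmbeddingSet()], [concatenateBlocks()], [splitSet()]
#' @export
setClass("EmbeddingSet",
  representation(
    blocks = "list", labels = "factor", rowIds = "character",
    split = "character"
  )
)

setValidity("EmbeddingSet", function(object) {
  msg <- character()
  b <- object@blocks
  if (length(b) == 0L) msg <- c(msg, "at least one encoder block is required")
  if (is.null(names(b)) || any(!nzchar(names(b))) || anyDuplicated(names(b)))
    msg <- c(msg, "blocks must carry unique, non-empty encoder ids as names")
  if (!all(vapply(b, is.matrix, logical(1))))
    msg <- c(msg, "every block must be a numeric matrix")
  nr <- unique(vapply(b, nrow, integer(1)))
  if (length(nr) > 1L)
    msg <- c(msg, "all blocks must have the same number of rows")
  n <- if (length(nr)) nr[1L] else 0L
  if (any(vapply(b, function(m) any(!is.finite(m)), logical(1))))
    msg <- c(msg, "blocks must contain only finite values")
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must equal the number of rows")
  if (length(object@rowIds) != n || anyDuplicated(object@rowIds))
    msg <- c(msg, "rowIds must be unique and one per row")
  if (length(object@split) != n)
    msg <- c(msg, "split length must equal the number of rows")
  if (length(msg)) msg else TRUE
})

#' Entropy-weighted k-NN classifier index
#'
#' The queryable classifier: the concatenated training matrix, its labels and
#' class counts, the frozen inverse-frequency class weights, the search
#' configuration and the retrieval backend (an HNSW graph for the L2 metric,
#' an exact flat scan for Canberra). Class weights are computed once when the
#' index is built, never per query.
#'
#' @slot data numeric matrix, N x d concatenated embeddings.
#' @slot labels factor, one class label per database row.
#' @slot classWeights named numeric, `w_i = N / (C * N_i)` when reweighting is
#'   enabled, otherwise all 1.
#' @slot reweighted logical flag.
#' @slot config [SearchConfig-class].
#' @slot backend `"hnsw"` or `"flat"`.
#' @slot ptr external pointer to the HNSW graph (`NULL` for flat backend).
#' @slot blockLayout named list of `c(start, end)` zero-based column offsets
#'   of each encoder block inside `data`.
#' @slot seed integer seed used for the HNSW level draws.
#'
#' @seealso [buildIndex()], [adaptivePredict()], [searchNeighbors()]
#' @export
setClass("EwcIndex",
  representation(
    data = "matrix", labels = "factor", classWeights = "numeric",
    reweighted = "logical", config = "SearchConfig", backend = "character",
    ptr = "ANY", blockLayout = "list", seed = "integer"
  )
)

setValidity("EwcIndex", function(object) {
  msg <- character()
  if (nrow(object@data) == 0L) msg <- c(msg, "index database is empty")
  if (length(object@labels) != nrow(object@data))
    msg <- c(msg, "labels length must equal the number of database rows")
  if (!setequal(names(object@classWeights), levels(object@labels)))
    msg <- c(msg, "classWeights must be named by the class levels")
  if (any(object@classWeights <= 0))
    msg <- c(msg, "class weights must be positive")
  if (!object@backend %in% c("hnsw", "flat"))
    msg <- c(msg, "backend must be 'hnsw' or 'flat'")
  if (length(msg)) msg else TRUE
})

#' Class-by-class mean cosine-similarity matrix
#'
#' Cell (a, b) is the mean cosine similarity over all cross pairs of
#' PCA-projected embeddings from classes a and b; diagonal cells average over
#' unordered distinct within-class pairs (self pairs excluded, they are
#' identically 1).
#'
#' @slot classes character, ordered class labels.
#' @slot similarity numeric C x C symmetric matrix in `[-1, 1]`.
#' @slot nPairs numeric C x C matrix of pair counts behind each cell.
#' @slot pcaDims integer, dimensionality of the PCA projection used.
#'
#' @seealso [classCosineMatrix()], [separability()]
#' @export
setClass("ClassSimilarityMatrix",
  representation(
    classes = "character", similarity = "matrix", nPairs = "matrix",
    pcaDims = "integer"
  )
)

setValidity("ClassSimilarityMatrix", function(object) {
  msg <- character()
  C <- length(object@classes)
  if (!all(dim(object@similarity) == c(C, C)))
    msg <- c(msg, "similarity must be C x C")
  if (max(abs(object@similarity - t(object@similarity))) > 1e-8)
    msg <- c(msg, "similarity must be symmetric")
  if (any(object@similarity < -1 - 1e-8) || any(object@similarity > 1 + 1e-8))
    msg <- c(msg, "similarities must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
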