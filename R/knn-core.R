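#' Build a search configuration
#'
#' @param kMin smallest neighbourhood size, >= 2.
#' @param kMax largest neighbourhood size.
#' @param entropyThreshold stopping threshold on the normalized neighbour
#'   entropy, in `[0, 1]`; the search stops as soon as the entropy is
#'   strictly below it.
#' @param metric `"L2"` or `"Canberra"`.
#' @param growthFactor multiplicative k schedule (> 1, default 2).
#' @param hnswM,efConstruction,efSearch HNSW graph parameters; `efSearch = NA`
#'   uses `max(2 * k, 128)` at query time.
#' @return A [SearchConfig-class].
#' @examples
#' searchConfig(kMin = 3, kMax = 100, entropyThreshold = 0.6,
#'              metric = "Canberra")
#' @export
searchConfig <- function(kMin = 3, kMax = 1000, entropyThreshold = 0.3,
                         metric = c("L2", "Canberra"), growthFactor = 2,
                         hnswM = 32, efConstruction = 200,
                         efSearch = NA_integer_) {
  metric <- match.arg(metric)
  new("SearchConfig",
    kMin = as.integer(kMin), kMax = as.integer(kMax),
    entropyThreshold = as.numeric(entropyThreshold), metric = metric,
    growthFactor = as.numeric(growthFactor), hnswM = as.integer(hnswM),
    efConstruction = as.integer(efConstruction),
    efSearch = as.integer(efSearch)
  )
}

setMethod("show", "SearchConfig", function(object) {
  cat("SearchConfig: k in [", object@kMin, ", ", object@kMax,
      "], entropy threshold ", object@entropyThreshold, ", metric ",
      object@metric, ", growth x", object@growthFactor, "\n", sep = "")
})

#' Inverse-frequency class weights
#'
#' With reweighting enabled the weight of class i is `w_i = N / (C * N_i)`,
#' where N is the total sample count, C the number of classes and `N_i` the
#' count of class i; minority classes thus receive larger vote weight, and
#' the weights satisfy `sum_i w_i * N_i = N`. With reweighting disabled all
#' weights are 1. Weights are computed once when the database is built.
#'
#' @param labels factor (or coercible) of database labels.
#' @param reweight logical flag.
#' @return Named numeric vector of per-class weights.
#' @examples
#' computeClassWeights(rep(c("a", "b"), c(90, 10)))
#' @export
computeClassWeights <- function(labels, reweight = TRUE) {
  labels <- as.factor(labels)
  if (length(labels) == 0L) stop("empty database: no labels to weight")
  counts <- table(labels)
  if (any(counts == 0L)) stop("every class level must have a positive count")
  if (!reweight)
    return(setNames(rep(1, length(counts)), names(counts)))
  N <- length(labels)
  C <- length(counts)
  setNames(as.numeric(N / (C * counts)), names(counts))
}

#' Normalized Shannon entropy of a neighbour label multiset
#'
#' `H_norm = -sum_i p_i log(p_i) / log(k)` over the classes observed among
#' the k labels (`0 * log 0 := 0`), so the value lies in `[0, 1]` regardless
#' of k: 0 for a pure neighbourhood, 1 when all k labels are distinct.
#'
#' @param labels vector of k >= 2 neighbour class labels.
#' @return Scalar in `[0, 1]`.
#' @examples
#' normalizedEntropy(c("A", "A", "A", "B")) # 0.4056
#' @export
normalizedEntropy <- function(labels) {
  k <- length(labels)
  if (k < 2L)
    stop("normalized entropy needs k >= 2 labels (log(1) = 0 denominator)")
  p <- tabulate(factor(as.character(labels)))
  p <- p[p > 0] / k
  h <- -sum(p * log(p)) / log(k)
  min(max(h, 0), 1)
}

#' Certainty percentage from a normalized entropy
#'
#' @param entropy scalar in `[0, 1]`.
#' @return `(1 - entropy) * 100`.
#' @export
certainty <- function(entropy) {
  if (any(!is.finite(entropy)) || any(entropy < 0) || any(entropy > 1))
    stop("entropy must lie in [0, 1]")
  (1 - entropy) * 100
}

#' Class-weighted neighbour vote
#'
#' `y_pred = argmax_l sum_j w_{y_j} 1{y_j = l}`: each neighbour contributes
#' its class weight; distances never enter the score. Ties are broken by the
#' smaller summed neighbour distance among the tied classes (when distances
#' are supplied), then lexicographically.
#'
#' @param labels neighbour class labels.
#' @param weights named class weights (see [computeClassWeights()]).
#' @param distances optional neighbour distances, used only for tie-breaks.
#' @return The winning class label (character scalar).
#' @examples
#' weightedVote(c("A", "A", "A", "B"), c(A = 100 / 180, B = 5))
#' @export
weightedVote <- function(labels, weights, distances = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("neighbour set is empty")
  missing <- setdiff(unique(labels), names(weights))
  if (length(missing))
    stop("no class weight for observed label(s): ",
         paste(missing, collapse = ", "))
  scores <- vapply(split(seq_along(labels), labels),
                   function(ix) weights[[labels[ix[1L]]]] * length(ix),
                   numeric(1))
  top <- names(scores)[scores >= max(scores) - 1e-12]
  if (length(top) > 1L && !is.null(distances)) {
    sums <- vapply(top, function(l) sum(distances[labels == l]), numeric(1))
    top <- top[sums <= min(sums) + 1e-12]
  }
  sort(top)[1L]
}

.metricCode <- function(metric) match(metric, c("L2", "Canberra")) - 1L

#' Build the entropy-weighted k-NN classifier index
#'
#' Concatenates the requested encoder blocks (or takes a ready matrix),
#' freezes the inverse-frequency class weights, and constructs the retrieval
#' backend: an HNSW graph for the L2 metric, an exact flat scan for Canberra
#' (graph indices over non-metric-friendly distances are not reliable, and
#' the behavioural contract is metric-correct retrieval).
#'
#' @param x an [EmbeddingSet-class] (its `train` split if tagged, otherwise
#'   all rows) or a numeric matrix.
#' @param labels class labels, required when `x` is a matrix.
#' @param config a [SearchConfig-class].
#' @param subset encoder ids to concatenate when `x` is an `EmbeddingSet`.
#' @param reweight logical, enable inverse-frequency vote weights.
#' @param seed integer seed for the HNSW level draws (determinism).
#' @param useTrainSplit when `x` is an `EmbeddingSet`, restrict to rows
#'   tagged `"train"` if such rows exist (default `TRUE`).
#' @return An [EwcIndex-class].
#' @examples
#' cfg <- syntheticEmbeddingConfig(c("a", "b"), c(40, 40), c(e = 4),
#'                                 classSeparation = 6, seed = 1)
#' es <- generateEmbeddingSet(cfg)
#' idx <- buildIndex(es, config = searchConfig(kMin = 3, kMax = 20))
#' @export
buildIndex <- function(x, labels = NULL, config = searchConfig(),
                       subset = NULL, reweight = TRUE, seed = 1L,
                       useTrainSplit = TRUE) {
  validObject(config)
  layout <- list()
  if (is(x, "EmbeddingSet")) {
    if (useTrainSplit && any(!is.na(splitTags(x)) & splitTags(x) == "train"))
      x <- splitSet(x, "train")
    if (is.null(subset)) subset <- encoderIds(x)
    mat <- concatenateBlocks(x, subset)
    layout <- attr(mat, "blockLayout")
    attr(mat, "blockLayout") <- NULL
    labels <- labels(x)
  } else {
    mat <- as.matrix(x)
    if (is.null(labels)) stop("labels are required when x is a matrix")
  }
  if (nrow(mat) == 0L) stop("cannot build an index from an empty database")
  if (any(!is.finite(mat))) stop("database rows must be finite")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(mat))
    stop("labels length must equal the number of rows")
  weights <- computeClassWeights(labels, reweight = reweight)
  backend <- if (config@metric == "L2") "hnsw" else "flat"
  ptr <- NULL
  if (backend == "hnsw")
    ptr <- .hnsw_build(mat, config@hnswM, config@efConstruction,
                       .metricCode(config@metric), as.integer(seed))
  new("EwcIndex",
    data = mat, labels = labels, classWeights = weights,
    reweighted = reweight, config = config, backend = backend, ptr = ptr,
    blockLayout = layout, seed = as.integer(seed)
  )
}

setMethod("show", "EwcIndex", function(object) {
  cat("EwcIndex:", nrow(object@data), "x", ncol(object@data),
      "database,", object@backend, "backend,", object@config@metric,
      "metric\n")
  cnt <- table(object@labels)
  cat("  classes:",
      paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
  cat("  reweighting:", if (object@reweighted) "on" else "off", "\n")
})

# The HNSW graph lives in C++ memory; after deserialization the external
# pointer is void and the graph is rebuilt deterministically from the stored
# matrix and seed.
.backendPtr <- function(index) {
  if (index@backend != "hnsw") return(NULL)
  if (!is.null(index@ptr) && .hnsw_valid(index@ptr)) return(index@ptr)
  .hnsw_build(index@data, index@config@hnswM, index@config@efConstruction,
              .metricCode(index@config@metric), index@seed)
}

#' Retrieve the k nearest database neighbours of each query
#'
#' @param index an [EwcIndex-class].
#' @param queries numeric matrix of query rows (index dimensionality).
#' @param k neighbourhood size; clamped to the database size with a warning.
#' @param efSearch HNSW beam width override; default `max(2 * k, 128)` or the
#'   configured value.
#' @return List with `ids` (n x k, 1-based database rows), `distances`
#'   (non-decreasing along each row) and `labels` (n x k character).
#' @export
searchNeighbors <- function(index, queries, k, efSearch = NULL) {
  stopifnot(is(index, "EwcIndex"))
  queries <- if (is.null(dim(queries))) matrix(queries, 1L) else
    as.matrix(queries)
  if (ncol(queries) != ncol(index@data))
    stop("query dimensionality (", ncol(queries),
         ") does not match the index (", ncol(index@data), ")")
  if (any(!is.finite(queries))) stop("queries must be finite")
  N <- nrow(index@data)
  if (k > N) {
    warning("k = ", k, " exceeds the database size; clamped to ", N)
    k <- N
  }
  k <- as.integer(k)
  if (index@backend == "hnsw") {
    ef <- if (!is.null(efSearch)) as.integer(efSearch)
          else if (!is.na(index@config@efSearch)) index@config@efSearch
          else max(2L * k, 128L)
    res <- .hnsw_query(.backendPtr(index), queries, k, ef)
  } else {
    res <- .flat_query(index@data, queries, k, .metricCode(index@config@metric))
  }
  lab <- matrix(as.character(index@labels)[res$ids], nrow(queries), k)
  list(ids = res$ids, distances = res$distances, labels = lab)
}

.kSchedule <- function(kMin, kMax, growth) {
  ks <- kMin
  while (ks[length(ks)] < kMax) {
    nxt <- min(ceiling(ks[length(ks)] * growth), kMax)
    ks <- c(ks, nxt)
  }
  as.integer(ks)
}

#' Entropy-guided adaptive k-NN prediction
#'
#' For each query, k starts at `kMin`; after retrieving k neighbours the
#' normalized entropy of their labels is computed, and the search stops as
#' soon as it falls strictly below the configured threshold or `kMax` is
#' reached — otherwise k is multiplied by the growth factor (final step
#' clamped to `kMax`). The prediction is the class-weighted vote over the
#' last retrieved neighbour set; the entropy that stopped the search is
#' reported as a certainty percentage `(1 - H_norm) * 100`. The entropy uses
#' raw label frequencies, not reweighted ones, so the uncertainty readout is
#' independent of the vote rebalancing.
#'
#' @param index an [EwcIndex-class].
#' @param queries numeric matrix (or an [EmbeddingSet-class], concatenated
#'   with the encoder subset the index was built from).
#' @param returnNeighbors if `TRUE`, attach the final neighbour sets as the
#'   `"neighbors"` attribute.
#' @return A `data.frame` with one row per query: `predicted_label`,
#'   `k_used`, `entropy`, `certainty_percent`.
#' @examples
#' cfg <- syntheticEmbeddingConfig(c("a", "b"), c(40, 40), c(e = 4),
#'                                 classSeparation = 8, seed = 1)
#' es <- generateEmbeddingSet(cfg)
#' idx <- buildIndex(es, config = searchConfig(kMin = 3, kMax = 20))
#' preds <- adaptivePredict(idx, splitSet(es, "val"))
#' head(preds)
#' @export
adaptivePredict <- function(index, queries, returnNeighbors = FALSE) {
  stopifnot(is(index, "EwcIndex"))
  rowIds <- NULL
  if (is(queries, "EmbeddingSet")) {
    rowIds <- queries@rowIds
    subset <- if (length(index@blockLayout)) names(index@blockLayout)
              else encoderIds(queries)
    queries <- concatenateBlocks(queries, subset)
  }
  queries <- if (is.null(dim(queries))) matrix(queries, 1L) else
    as.matrix(queries)
  nq <- nrow(queries)
  cfg <- index@config
  N <- nrow(index@data)
  kMin <- cfg@kMin
  kMax <- cfg@kMax
  if (kMax > N) {
    warning("kMax = ", kMax, " exceeds the database size; clamped to ", N)
    kMax <- N
  }
  if (kMin > N) kMin <- N
  schedule <- .kSchedule(kMin, kMax, cfg@growthFactor)

  pred <- character(nq)
  kUsed <- integer(nq)
  ent <- numeric(nq)
  neigh <- if (returnNeighbors) vector("list", nq) else NULL
  active <- seq_len(nq)
  for (si in seq_along(schedule)) {
    if (!length(active)) break
    k <- schedule[si]
    res <- searchNeighbors(index, queries[active, , drop = FALSE], k)
    h <- apply(res$labels, 1L, normalizedEntropy)
    done <- h < cfg@entropyThreshold | si == length(schedule)
    for (j in which(done)) {
      qi <- active[j]
      pred[qi] <- weightedVote(res$labels[j, ], index@classWeights,
                               res$distances[j, ])
      kUsed[qi] <- k
      ent[qi] <- h[j]
      if (returnNeighbors)
        neigh[[qi]] <- list(ids = res$ids[j, ], labels = res$labels[j, ],
                            distances = res$distances[j, ], k = k)
    }
    active <- active[!done]
  }
  out <- data.frame(
    row_id = if (!is.null(rowIds)) rowIds else paste0("q", seq_len(nq)),
    predicted_label = pred,
    k_used = kUsed,
    entropy = ent,
    certainty_percent = certainty(ent),
    stringsAsFactors = FALSE
  )
  if (returnNeighbors) attr(out, "neighbors") <- neigh
  out
}

#' Macro-averaged classification metrics
#'
#' `macroAccuracy` is the unweighted mean over true classes of the per-class
#' recall (the "average of class-specific accuracies"); `macroPrecision` is
#' the unweighted mean over classes of the per-predicted-class precision.
#' Both are percentages, insensitive to class imbalance. Classes never
#' predicted contribute precision 0 with a warning.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @return Scalar percentage.
#' @examples
#' macroAccuracy(c("a", "a", "b"), c("a", "b", "b")) # (1/2 + 1) / 2 * 100
#' @export
macroAccuracy <- function(yTrue, yPred) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (length(yTrue) == 0L) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  recalls <- vapply(unique(yTrue),
                    function(cl) mean(yPred[yTrue == cl] == cl), numeric(1))
  mean(recalls) * 100
}

#' @rdname macroAccuracy
#' @export
macroPrecision <- function(yTrue, yPred) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (length(yTrue) == 0L) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  classes <- sort(unique(c(yTrue, yPred)))
  prec <- vapply(classes, function(cl) {
    hit <- yPred == cl
    if (!any(hit)) return(NA_real_)
    mean(yTrue[hit] == cl)
  }, numeric(1))
  if (anyNA(prec)) {
    warning("class(es) never predicted contribute precision 0: ",
            paste(classes[is.na(prec)], collapse = ", "))
    prec[is.na(prec)] <- 0
  }
  mean(prec) * 100
}

#' Persist / restore a classifier index as plain-text files
#'
#' Writes the concatenated database at full precision (`data.csv`), and a
#' `meta.json` with labels, class weights, search configuration, block
#' layout, backend and seed. `loadIndex` rebuilds the HNSW graph
#' deterministically from the stored matrix and seed.
#'
#' @param index an [EwcIndex-class].
#' @param path directory to create/read.
#' @return `saveIndex` returns `path` invisibly; `loadIndex` an `EwcIndex`.
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "EwcIndex"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- index@data
  df <- as.data.frame(matrix(sprintf("%.17g", m), nrow = nrow(m),
                             ncol = ncol(m)))
  names(df) <- paste0("f", seq_len(ncol(m)))
  write.csv(df, file.path(path, "data.csv"), row.names = FALSE, quote = FALSE)
  cfg <- index@config
  meta <- list(
    labels = as.character(index@labels),
    class_weights = as.list(index@classWeights),
    reweighted = index@reweighted,
    backend = index@backend,
    seed = index@seed,
    block_layout = lapply(index@blockLayout, as.list),
    config = list(
      k_min = cfg@kMin, k_max = cfg@kMax,
      entropy_threshold = cfg@entropyThreshold, metric = cfg@metric,
      growth_factor = cfg@growthFactor, hnsw_m = cfg@hnswM,
      ef_construction = cfg@efConstruction,
      ef_search = if (is.na(cfg@efSearch)) NULL else cfg@efSearch
    )
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  df <- read.csv(file.path(path, "data.csv"))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  cfg <- searchConfig(
    kMin = meta$config$k_min, kMax = meta$config$k_max,
    entropyThreshold = meta$config$entropy_threshold,
    metric = meta$config$metric, growthFactor = meta$config$growth_factor,
    hnswM = meta$config$hnsw_m, efConstruction = meta$config$ef_construction,
    efSearch = if (length(meta$config$ef_search)) meta$config$ef_search
               else NA_integer_
  )
  layout <- lapply(meta$block_layout, function(x)
    c(start = x$start, end = x$end))
  idx <- buildIndex(m, labels = unlist(meta$labels), config = cfg,
                    reweight = meta$reweighted, seed = meta$seed)
  idx@blockLayout <- layout
  idx
}
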