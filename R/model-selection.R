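#' Enumerate all non-empty encoder subsets
#'
#' Subsets are emitted in a deterministic order (by size, then by canonical
#' encoder positions), each subset itself in canonical (registration) order.
#' A guard refuses more than `maxEncoders` ids, since the power set doubles
#' per encoder.
#'
#' @param encoderIds character vector of encoder ids (canonical order).
#' @param maxEncoders guard limit (default 12).
#' @param allowLarge set `TRUE` to override the guard.
#' @return List of character vectors; length `2^n - 1`.
#' @examples
#' length(enumerateSubsets(letters[1:6])) # 63
#' @export
enumerateSubsets <- function(encoderIds, maxEncoders = 12L,
                             allowLarge = FALSE) {
  encoderIds <- as.character(encoderIds)
  n <- length(encoderIds)
  if (n < 1L) stop("need at least one encoder id")
  if (anyDuplicated(encoderIds)) stop("encoder ids must be unique")
  if (n > maxEncoders && !allowLarge)
    stop("refusing to enumerate 2^", n, " - 1 subsets; ",
         "set allowLarge = TRUE to override")
  out <- list()
  for (size in seq_len(n)) {
    cmb <- combn(n, size)
    for (j in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- encoderIds[cmb[, j]]
  }
  out
}

#' Exhaustive encoder-subset selection by validation macro accuracy
#'
#' Evaluates every non-empty subset of the available encoders: concatenate
#' the training blocks, build the classifier index, predict the validation
#' rows with the adaptive entropy-guided search, and score validation macro
#' accuracy. The winner (the *incumbent*) is the subset with the highest
#' score; ties are broken by fewer encoders, then enumeration order. The
#' search keeps the supplied `config` fixed across subsets.
#'
#' @param train,val [EmbeddingSet-class] objects sharing encoder ids and
#'   classes (e.g. the `train` and `val` splits of one set).
#' @param config a [SearchConfig-class] used for every subset.
#' @param reweight logical, inverse-frequency vote weights.
#' @param seed integer seed for index construction.
#' @param maxEncoders,allowLarge guard, see [enumerateSubsets()].
#' @return A list with `subset` (winning ids), `valMacroAccuracy`, `config`,
#'   and `leaderboard` (a `data.frame`, one row per subset, ranked).
#' @examples
#' cfg <- syntheticEmbeddingConfig(c("a", "b"), c(60, 60),
#'   blockDims = c(sig = 4, noise = 4), informativeBlocks = "sig",
#'   classSeparation = 8, seed = 3)
#' es <- generateEmbeddingSet(cfg, c(0.7, 0.25, 0.05))
#' sel <- selectBestSubset(splitSet(es, "train"), splitSet(es, "val"),
#'                         searchConfig(kMin = 3, kMax = 20))
#' sel$subset
#' @export
selectBestSubset <- function(train, val, config = searchConfig(),
                             reweight = TRUE, seed = 1L, maxEncoders = 12L,
                             allowLarge = FALSE) {
  stopifnot(is(train, "EmbeddingSet"), is(val, "EmbeddingSet"))
  if (nSamples(val) == 0L) stop("validation split is empty")
  if (!setequal(encoderIds(train), encoderIds(val)))
    stop("train and val must share encoder ids")
  subsets <- enumerateSubsets(encoderIds(train), maxEncoders, allowLarge)
  acc <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    idx <- buildIndex(train, config = config, subset = subsets[[i]],
                      reweight = reweight, seed = seed,
                      useTrainSplit = FALSE)
    preds <- adaptivePredict(idx, concatenateBlocks(val, subsets[[i]]))
    acc[i] <- macroAccuracy(labels(val), preds$predicted_label)
  }
  sizes <- lengths(subsets)
  ord <- order(-acc, sizes, seq_along(subsets))
  leaderboard <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    n_encoders = sizes,
    val_macro_accuracy = acc,
    k_min = config@kMin, k_max = config@kMax,
    threshold = config@entropyThreshold, metric = config@metric,
    stringsAsFactors = FALSE
  )[ord, ]
  leaderboard$rank <- seq_len(nrow(leaderboard))
  rownames(leaderboard) <- NULL
  list(
    subset = subsets[[ord[1L]]],
    valMacroAccuracy = acc[ord[1L]],
    config = config,
    leaderboard = leaderboard
  )
}

#' Named hyperparameter presets
#'
#' The incumbent configurations found for the published imaging regimes
#' (encoder subset, k bounds, entropy threshold, metric, reweighting), plus
#' the recommended fallback combination `dino-convnext-swin` for new data.
#' Shipped as a YAML file under `extdata/presets.yaml`.
#'
#' @param name preset name; `NULL` lists all presets.
#' @return A list with `encoders`, a [SearchConfig-class] in `config`, and
#'   `reweight`; or a named list of all presets.
#' @examples
#' names(ewcPresets())
#' ewcPresets("cell-death-nanolive")$config
#' @export
ewcPresets <- function(name = NULL) {
  path <- system.file("extdata", "presets.yaml", package = "entroKNN",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  build <- function(p) list(
    encoders = unlist(p$encoders),
    config = searchConfig(
      kMin = p$k_min, kMax = p$k_max,
      entropyThreshold = p$entropy_threshold, metric = p$metric
    ),
    reweight = isTRUE(p$reweight)
  )
  if (is.null(name)) return(lapply(raw, build))
  if (!name %in% names(raw))
    stop("unknown preset '", name, "'; available: ",
         paste(names(raw), collapse = ", "))
  build(raw[[name]])
}
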