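#' Construct an EmbeddingSet
#'
#' @param blocks named list of numeric matrices (one per encoder), all with
#'   the same number of rows. The registration order of this list is the
#'   canonical encoder order used by [concatenateBlocks()] and
#'   [enumerateSubsets()].
#' @param labels class label per row (coerced to factor).
#' @param rowIds optional unique row identifiers; defaults to
#'   `"r1", "r2", ...`.
#' @param split optional split tag per row (`"train"`, `"val"`, `"test"`,
#'   `"transfer"`); defaults to `NA`.
#'
#' @return An [EmbeddingSet-class] object.
#' @examples
#' es <- EmbeddingSet(
#'   blocks = list(A = matrix(rnorm(20), 5), B = matrix(rnorm(15), 5)),
#'   labels = c("x", "x", "y", "y", "y")
#' )
#' encoderIds(es)
#' @export
EmbeddingSet <- function(blocks, labels, rowIds = NULL, split = NULL) {
  blocks <- lapply(blocks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- if (length(blocks)) nrow(blocks[[1L]]) else 0L
  if (is.null(rowIds))
    rowIds <- if (n > 0L) paste0("r", seq_len(n)) else character(0)
  if (is.null(split)) split <- rep(NA_character_, n)
  new("EmbeddingSet",
    blocks = blocks, labels = as.factor(labels),
    rowIds = as.character(rowIds), split = as.character(split)
  )
}

#' @rdname EmbeddingSet
#' @export
setMethod("encoderIds", "EmbeddingSet", function(object) names(object@blocks))

#' @rdname EmbeddingSet
#' @export
setMethod("nSamples", "EmbeddingSet", function(object) {
  if (length(object@blocks)) nrow(object@blocks[[1L]]) else 0L
})

#' @rdname EmbeddingSet
#' @export
setMethod("blockMatrix", "EmbeddingSet", function(object, encoderId) {
  if (!encoderId %in% names(object@blocks))
    stop("unknown encoder id: ", encoderId)
  object@blocks[[encoderId]]
})

#' @rdname EmbeddingSet
#' @export
setMethod("splitTags", "EmbeddingSet", function(object) object@split)

#' @rdname EmbeddingSet
#' @export
setMethod("labels", "EmbeddingSet", function(object, ...) object@labels)

setMethod("show", "EmbeddingSet", function(object) {
  dims <- vapply(object@blocks, ncol, integer(1))
  cat("EmbeddingSet with", nSamples(object), "samples,",
      length(object@blocks), "encoder block(s)\n")
  cat("  blocks:", paste0(names(dims), "(", dims, ")", collapse = ", "), "\n")
  cat("  classes:", paste(levels(object@labels), collapse = ", "), "\n")
  sp <- table(object@split, useNA = "ifany")
  cat("  split:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
})

#' @rdname EmbeddingSet
#' @param x an `EmbeddingSet`.
#' @param i row index (integer, logical or rowId character).
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "EmbeddingSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@rowIds)
  new("EmbeddingSet",
    blocks = lapply(x@blocks, function(m) m[i, , drop = FALSE]),
    labels = droplevels(x@labels[i]), rowIds = x@rowIds[i],
    split = x@split[i]
  )
})

#' Extract one split of an embedding set
#'
#' @param set an [EmbeddingSet-class].
#' @param which split tag to keep (`"train"`, `"val"`, `"test"`, ...).
#' @return An `EmbeddingSet` with only the rows carrying that tag.
#' @export
splitSet <- function(set, which) {
  stopifnot(is(set, "EmbeddingSet"))
  keep <- !is.na(set@split) & set@split == which
  if (!any(keep)) stop("no rows carry split tag '", which, "'")
  set[keep]
}

#' Column layout of encoder blocks in a concatenation
#'
#' @param set an [EmbeddingSet-class].
#' @param subset encoder ids, in any order; they are used in canonical
#'   (registration) order.
#' @return Named list of zero-based, half-open `c(start, end)` column offsets.
#' @export
blockLayout <- function(set, subset = encoderIds(set)) {
  subset <- canonicalSubset(set, subset)
  dims <- vapply(set@blocks[subset], ncol, integer(1))
  ends <- cumsum(dims)
  starts <- ends - dims
  layout <- mapply(function(s, e) c(start = s, end = e), starts, ends,
                   SIMPLIFY = FALSE)
  names(layout) <- subset
  layout
}

canonicalSubset <- function(set, subset) {
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stop("encoder subset must be non-empty")
  unknown <- setdiff(subset, encoderIds(set))
  if (length(unknown))
    stop("unknown encoder id(s): ", paste(unknown, collapse = ", "))
  intersect(encoderIds(set), subset) # canonical registration order
}

#' Concatenate encoder blocks column-wise
#'
#' Juxtaposes the selected blocks in canonical (registration) order, exactly
#' as stored: no scaling, centering or normalization is applied. An optional
#' per-row L2 normalization of the concatenated vector is available but off
#' by default, matching the method's use of raw features.
#'
#' @param set an [EmbeddingSet-class].
#' @param subset encoder ids to include (default: all).
#' @param l2Normalize logical, opt-in row-wise L2 normalization of the
#'   concatenated matrix (default `FALSE`).
#' @return A numeric matrix with `attr(, "blockLayout")` recording the
#'   zero-based column offsets of each block.
#' @examples
#' es <- EmbeddingSet(list(A = matrix(1:8, 2), B = matrix(1:6, 2)), c("x", "y"))
#' m <- concatenateBlocks(es)
#' attr(m, "blockLayout")
#' @export
concatenateBlocks <- function(set, subset = encoderIds(set),
                              l2Normalize = FALSE) {
  stopifnot(is(set, "EmbeddingSet"))
  subset <- canonicalSubset(set, subset)
  out <- do.call(cbind, set@blocks[subset])
  if (l2Normalize) {
    nrm <- sqrt(rowSums(out^2))
    nrm[nrm == 0] <- 1
    out <- out / nrm
  }
  attr(out, "blockLayout") <- blockLayout(set, subset)
  out
}

#' Write / read an embedding set as plain-text files
#'
#' A directory holding one CSV per encoder block (first column `row_id`,
#' remaining columns features at full precision), a `manifest.csv`
#' (`row_id,label,split`) and a `layout.json` sidecar recording the canonical
#' encoder order and block dimensions. `readEmbeddingSet(writeEmbeddingSet(x))`
#' reproduces matrices bit-exactly and labels exactly.
#'
#' @param set an [EmbeddingSet-class].
#' @param path directory to create/read.
#' @return `writeEmbeddingSet` returns `path` invisibly; `readEmbeddingSet`
#'   returns an `EmbeddingSet`.
#' @export
writeEmbeddingSet <- function(set, path) {
  stopifnot(is(set, "EmbeddingSet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "blocks"), showWarnings = FALSE)
  for (id in encoderIds(set)) {
    m <- set@blocks[[id]]
    df <- data.frame(row_id = set@rowIds, check.names = FALSE)
    if (ncol(m)) {
      feat <- as.data.frame(
        matrix(sprintf("%.17g", m), nrow = nrow(m), ncol = ncol(m)),
        stringsAsFactors = FALSE
      )
      names(feat) <- paste0("f", seq_len(ncol(m)))
      df <- cbind(df, feat)
    }
    write.csv(df, file.path(path, "blocks", paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  manifest <- data.frame(
    row_id = set@rowIds, label = as.character(set@labels), split = set@split
  )
  write.csv(manifest, file.path(path, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  sidecar <- list(
    encoder_order = as.list(encoderIds(set)),
    block_dims = as.list(vapply(set@blocks, ncol, integer(1))),
    block_layout = lapply(blockLayout(set), as.list)
  )
  jsonlite::write_json(sidecar, file.path(path, "layout.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeEmbeddingSet
#' @export
readEmbeddingSet <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "layout.json"))
  order <- unlist(sidecar$encoder_order)
  manifest <- read.csv(file.path(path, "manifest.csv"),
                       colClasses = "character")
  blocks <- list()
  for (id in order) {
    df <- read.csv(file.path(path, "blocks", paste0(id, ".csv")),
                   colClasses = c(row_id = "character"))
    if (nrow(df) != nrow(manifest) ||
        !identical(df$row_id, manifest$row_id))
      stop("row ids of block '", id, "' do not match the manifest")
    m <- as.matrix(df[, setdiff(names(df), "row_id"), drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    blocks[[id]] <- m
  }
  split <- manifest$split
  split[!nzchar(split) | split == "NA"] <- NA_character_
  EmbeddingSet(blocks, labels = manifest$label, rowIds = manifest$row_id,
               split = split)
}
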