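#' @rdname EmbeddingSet
#' @param object an object.
#' @export
setGeneric("encoderIds", function(object) standardGeneric("encoderIds"))

#' @rdname EmbeddingSet
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname EmbeddingSet
#' @param encoderId single encoder id.
#' @export
setGeneric("blockMatrix", function(object, encoderId)
  standardGeneric("blockMatrix"))

#' @rdname EmbeddingSet
#' @export
setGeneric("splitTags", function(object) standardGeneric("splitTags"))

#' @rdname ClassSimilarityMatrix
#' @param object an object.
#' @export
setGeneric("similarityMatrix", function(object)
  standardGeneric("similarityMatrix"))
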