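#' @rdname KmerCorpus-class
#' @param x a `KmerCorpus`
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))

#' @rdname KmerCorpus-class
#' @export
setGeneric("corpusInfo", function(x) standardGeneric("corpusInfo"))

#' @rdname EmbeddingTable-class
#' @param x an `EmbeddingTable`
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname EmbeddingTable-class
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname EmbeddingTable-class
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))

#' @describeIn KmerCorpus-class accessor for the sentence list.
setMethod("sentences", "KmerCorpus", function(x) x@sentences)

#' @describeIn KmerCorpus-class accessor for the per-sentence metadata.
setMethod("corpusInfo", "KmerCorpus", function(x) x@info)

#' @describeIn KmerCorpus-class number of sentences.
#' @export
setMethod("length", "KmerCorpus", function(x) length(x@sentences))

setMethod("show", "KmerCorpus", function(object) {
  n <- length(object@sentences)
  cat(sprintf("KmerCorpus with %d sentence%s from %d source sequence%s\n",
              n, if (n == 1) "" else "s",
              length(unique(object@info$source_id)),
              if (length(unique(object@info$source_id)) == 1) "" else "s"))
  if (n > 0) {
    tk <- lengths(object@sentences)
    cat(sprintf("  tokens per sentence: min %d / mean %.1f / max %d\n",
                min(tk), mean(tk), max(tk)))
    lab <- object@info$label
    cat(sprintf("  labels: %d methylated(0), %d unmethylated(1), %d NA\n",
                sum(lab == 0L, na.rm = TRUE), sum(lab == 1L, na.rm = TRUE),
                sum(is.na(lab))))
  }
  invisible(NULL)
})

#' @describeIn EmbeddingTable-class the vocabulary (token rownames).
setMethod("vocabulary", "EmbeddingTable", function(x) rownames(x@vectors))

#' @describeIn EmbeddingTable-class the embedding dimension D.
setMethod("embeddingDim", "EmbeddingTable", function(x) ncol(x@vectors))

#' @describeIn EmbeddingTable-class the V x D matrix of vectors.
setMethod("embeddingVectors", "EmbeddingTable", function(x) x@vectors)

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d tokens, dimension %d\n",
              nrow(object@vectors), ncol(object@vectors)))
  if (length(object@params))
    cat("  trained with:",
        paste(names(object@params), unlist(object@params),
              sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "GruModel", function(object) {
  H <- length(object@forward$br)
  cat(sprintf("GruModel (BiGRU classifier): D=%d, H=%d, embedding mode %s\n",
              ncol(object@embedding@vectors), H, object@embeddingMode))
  cat(sprintf("  vocabulary: %d tokens; head: %d -> 1 (sigmoid)\n",
              nrow(object@embedding@vectors), 2L * H))
  invisible(NULL)
})
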