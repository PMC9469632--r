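#' @import methods
NULL

#' KmerCorpus: a set of variable-length k-mer sentences
#'
#' Holds the tokenized sentences produced by segmenting DNA sequences,
#' together with per-sentence provenance: the source sequence id, the
#' strand origin (`forward` or `reverse_complement`), the replicate index
#' within the 2N-fold augmentation, and the class label (0 = methylated,
#' 1 = unmethylated, NA = unlabeled).
#'
#' @slot sentences list of character vectors; each element is one sentence
#'   of k-mer tokens whose concatenation reconstructs the originating
#'   (possibly reverse-complemented) sequence.
#' @slot info data.frame with columns `source_id`, `origin`,
#'   `replicate`, `label`, one row per sentence.
#'
#' @seealso [augmentSequence()], [buildCorpus()]
#' @export
setClass("KmerCorpus",
  slots = c(sentences = "list", info = "data.frame"))

setValidity("KmerCorpus", function(object) {
  msg <- character()
  if (length(object@sentences) != nrow(object@info))
    msg <- c(msg, "length(sentences) must equal nrow(info)")
  need <- c("source_id", "origin", "replicate", "label")
  if (!all(need %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else if (!all(object@info$origin %in% c("forward", "reverse_complement")))
    msg <- c(msg, "origin must be 'forward' or 'reverse_complement'")
  if (length(msg)) msg else TRUE
})

#' EmbeddingTable: k-mer to vector mapping
#'
#' The output of CBOW word2vec training over a k-mer sentence corpus:
#' a dense matrix with one D-dimensional row per vocabulary token.
#'
#' @slot vectors numeric matrix, rows named by k-mer token.
#' @slot params list of training metadata (dim, window, min_count,
#'   negative, epochs, learning rate, seed).
#'
#' @seealso [trainEmbeddings()], [lookupEmbedding()], [shuffleEmbedding()]
#' @export
setClass("EmbeddingTable",
  slots = c(vectors = "matrix", params = "list"))

setValidity("EmbeddingTable", function(object) {
  msg <- character()
  v <- object@vectors
  if (!is.numeric(v)) msg <- c(msg, "vectors must be a numeric matrix")
  if (ncol(v) < 1L) msg <- c(msg, "embedding dimension must be >= 1")
  if (nrow(v) > 0L && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msg <- c(msg, "vectors must have unique rownames (the vocabulary)")
  if (length(msg)) msg else TRUE
})

#' GruModel: a bidirectional GRU classifier
#'
#' All weights of the BiGRU sentence classifier: a forward and a backward
#' GRU cell (reset gate, update gate, candidate activation), a linear
#' head over the concatenated final hidden states followed by a sigmoid,
#' plus the embedding table feeding the recurrence and the flag saying
#' whether the embedding vectors are trained (`"V"`) or frozen (`"C"`).
#'
#' @slot forward,backward lists with elements `Wr, Ur, br, Wz, Uz, bz,
#'   Wh, Uh, bh` (matrices H x D, H x H and length-H vectors).
#' @slot headWeights numeric vector of length 2H.
#' @slot headBias numeric scalar.
#' @slot embedding an [EmbeddingTable-class].
#' @slot embeddingMode `"C"` (constant) or `"V"` (variable).
#' @slot config list of the hyper-parameters used to build/train the model.
#'
#' @seealso [initGruModel()], [trainCmic()], [predictCgi()]
#' @export
setClass("GruModel",
  slots = c(forward = "list", backward = "list",
            headWeights = "numeric", headBias = "numeric",
            embedding = "EmbeddingTable", embeddingMode = "character",
            config = "list"))

.cellOk <- function(cell, H, D) {
  need <- c("Wr", "Ur", "br", "Wz", "Uz", "bz", "Wh", "Uh", "bh")
  if (!all(need %in% names(cell))) return("cell is missing weight entries")
  for (w in c("Wr", "Wz", "Wh"))
    if (!all(dim(cell[[w]]) == c(H, D))) return(sprintf("%s must be H x D", w))
  for (u in c("Ur", "Uz", "Uh"))
    if (!all(dim(cell[[u]]) == c(H, H))) return(sprintf("%s must be H x H", u))
  for (b in c("br", "bz", "bh"))
    if (length(cell[[b]]) != H) return(sprintf("%s must have length H", b))
  if (!all(vapply(cell, function(x) all(is.finite(x)), logical(1))))
    return("all weights must be finite")
  TRUE
}

setValidity("GruModel", function(object) {
  H <- length(object@forward$br)
  D <- ncol(object@embedding@vectors)
  for (cell in list(object@forward, object@backward)) {
    ok <- .cellOk(cell, H, D)
    if (!isTRUE(ok)) return(ok)
  }
  if (length(object@headWeights) != 2L * H)
    return("headWeights must have length 2H")
  if (length(object@headBias) != 1L) return("headBias must be a scalar")
  if (!object@embeddingMode %in% c("C", "V"))
    return("embeddingMode must be 'C' or 'V'")
  TRUE
})
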