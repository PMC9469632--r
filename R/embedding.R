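#' Train k-mer embedding vectors (CBOW word2vec) over a sentence corpus
#'
#' Implements the embedding step of the pipeline: the variable-length
#' k-mer sentences are treated as text and fed to a continuous
#' bag-of-words word2vec model with negative sampling. With the default
#' `minCount = 1` every token occurring in the corpus receives a vector,
#' so lookups on the training corpus never miss.
#'
#' Training is unsupervised: class labels in the corpus are ignored.
#' Single-threaded and deterministic for a fixed `seed`.
#'
#' @param corpus a [KmerCorpus-class] or plain list of character vectors.
#' @param dim embedding dimension D (default 20).
#' @param window context window size (default 10).
#' @param minCount minimum token count to enter the vocabulary (default 1).
#' @param negative number of negative samples per target (default 5).
#' @param epochs training epochs over the corpus (default 5).
#' @param lr initial learning rate, linearly decayed (default 0.025).
#' @param whiten apply frequency-weighted PCA whitening to the trained
#'   vectors (default `TRUE`; skipped when the vocabulary is too small
#'   for a stable covariance estimate). k-mer corpora drawn from
#'   low-structure backgrounds give word2vec spaces dominated by a
#'   single frequency direction (the leading eigenvalue can exceed the
#'   rest by three orders of magnitude); whitening rebalances the axes
#'   so the distributional differences between tokens become usable by
#'   a downstream classifier.
#' @param seed RNG seed.
#' @return an [EmbeddingTable-class].
#' @export
trainEmbeddings <- function(corpus, dim = 20L, window = 10L, minCount = 1L,
                            negative = 5L, epochs = 5L, lr = 0.025,
                            whiten = TRUE, seed = 1L) {
  sent <- if (methods::is(corpus, "KmerCorpus")) corpus@sentences else corpus
  if (!length(sent)) stop("corpus is empty")
  toks <- unlist(sent, use.names = FALSE)
  if (!length(toks)) stop("corpus contains zero tokens")
  tab <- table(toks)
  keep <- names(tab)[tab >= minCount]
  if (!length(keep)) stop("no token reaches minCount")
  vocab <- sort(keep)
  counts <- as.integer(tab[vocab])
  ids <- match(toks, vocab)           # NA for below-minCount tokens
  lens <- lengths(sent)
  idsBySent <- split(ids, rep.int(seq_along(sent), lens))
  idsBySent <- lapply(idsBySent, function(v) as.integer(v[!is.na(v)]))
  idsBySent <- idsBySent[lengths(idsBySent) > 0L]
  vec <- cpp_cbow_train(idsBySent, counts, as.integer(dim),
                        as.integer(window), as.integer(negative),
                        as.integer(epochs), lr, as.integer(seed))
  rownames(vec) <- vocab
  whitened <- FALSE
  if (isTRUE(whiten) && length(vocab) > max(2L * dim, 50L)) {
    w <- counts / sum(counts)
    mu <- colSums(vec * w)
    vc <- sweep(vec, 2, mu)
    eig <- eigen(crossprod(vc * sqrt(w)), symmetric = TRUE)
    lam <- pmax(eig$values, max(eig$values) * 1e-8)
    vec <- vc %*% (eig$vectors %*% diag(1 / sqrt(lam), length(lam)))
    rownames(vec) <- vocab
    whitened <- TRUE
  }
  # usage-weighted RMS of the embedding coordinates: the typical input
  # magnitude seen by a downstream model (frequent tokens dominate both
  # the corpus and the vector norms)
  scale <- sqrt(sum(counts * rowSums(vec^2)) / (sum(counts) * ncol(vec)))
  methods::new("EmbeddingTable", vectors = vec,
               params = list(dim = as.integer(dim), window = as.integer(window),
                             min_count = as.integer(minCount),
                             negative = as.integer(negative),
                             epochs = as.integer(epochs), lr = lr,
                             seed = as.integer(seed), algorithm = "cbow-ns",
                             whitened = whitened, input_scale = scale))
}

#' Randomly shuffle the token-to-vector mapping of an embedding table
#'
#' Control scheme for probing how much the learned assignment matters:
#' the vocabulary and the multiset of vectors are kept, the mapping is
#' permuted uniformly at random.
#'
#' @param table an [EmbeddingTable-class].
#' @param seed RNG seed.
#' @return an [EmbeddingTable-class] with permuted mapping.
#' @export
shuffleEmbedding <- function(table, seed = 1L) {
  v <- table@vectors
  if (nrow(v) < 1L) stop("embedding table is empty")
  set.seed(seed)
  perm <- sample.int(nrow(v))
  shuffled <- v[perm, , drop = FALSE]
  rownames(shuffled) <- rownames(v)
  p <- table@params
  p$shuffled <- TRUE
  methods::new("EmbeddingTable", vectors = shuffled, params = p)
}

#' Look up embedding vectors for a sentence
#'
#' Maps each token of a sentence, in order, to its D-dimensional vector.
#'
#' @param table an [EmbeddingTable-class].
#' @param tokens character vector of k-mer tokens (one sentence).
#' @param oov out-of-vocabulary policy: `"zero"` substitutes a zero
#'   vector, `"strict"` raises an error naming the missing token.
#' @return numeric matrix, one row per token, D columns.
#' @export
lookupEmbedding <- function(table, tokens, oov = c("zero", "strict")) {
  oov <- match.arg(oov)
  if (!length(tokens)) stop("sentence is empty")
  idx <- match(tokens, rownames(table@vectors))
  if (anyNA(idx)) {
    if (oov == "strict")
      stop(sprintf("token(s) not in vocabulary: %s",
                   paste(unique(tokens[is.na(idx)]), collapse = ", ")))
    out <- matrix(0, nrow = length(tokens), ncol = ncol(table@vectors))
    ok <- !is.na(idx)
    out[ok, ] <- table@vectors[idx[ok], , drop = FALSE]
    rownames(out) <- tokens
    return(out)
  }
  out <- table@vectors[idx, , drop = FALSE]
  rownames(out) <- tokens
  out
}

# token ids (1-based into vocabulary; 0 = OOV) for a list of sentences;
# one match() over the flattened tokens so the vocabulary is hashed once
.sentenceIds <- function(sentList, vocab) {
  toks <- unlist(sentList, use.names = FALSE)
  idx <- match(toks, vocab)
  idx[is.na(idx)] <- 0L
  unname(split(as.integer(idx),
               rep.int(seq_along(sentList), lengths(sentList))))
}

#' Cosine similarity between two tokens of an embedding table
#'
#' @param table an [EmbeddingTable-class].
#' @param a,b tokens.
#' @return cosine similarity in \[-1, 1\].
#' @export
embeddingSimilarity <- function(table, a, b) {
  va <- lookupEmbedding(table, a, oov = "strict")[1, ]
  vb <- lookupEmbedding(table, b, oov = "strict")[1, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}
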