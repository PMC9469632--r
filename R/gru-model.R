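#' Full pipeline configuration
#'
#' Collects the hyper-parameters of the classifier and its training loop.
#' Defaults: N = 1000 sentences per strand, D = 20, H = 256, 2 epochs,
#' learning rate 1e-4 (Adam), batch 32, dropout 0.5 on the BiGRU output,
#' weight decay 0.01, k-mer length bounds 4..12, frozen embeddings (`"C"`).
#'
#' @param n N, sentences generated per strand per sequence.
#' @param dim embedding dimension D.
#' @param hidden GRU hidden dimension H.
#' @param epochs training epochs e.
#' @param lr Adam learning rate r.
#' @param batch batch size b.
#' @param dropout dropout rate d applied to the concatenated BiGRU output.
#' @param weightDecay decay coefficient alpha.
#' @param decayForm `"norm"` penalizes `alpha * ||w||_2` (the unsquared
#'   L2 norm, as in the loss used here); `"squared"` the conventional
#'   `alpha * ||w||_2^2`.
#' @param lrSchedule `"constant"` (default) or `"onecycle"` (linear
#'   warmup over the first 20% of updates to `lr`, then linear decay to
#'   `lr/20`); the one-cycle schedule is useful when the total update
#'   budget is small.
#' @param kmin,kmax token length bounds.
#' @param window word2vec context window.
#' @param minCount word2vec minimum token count.
#' @param embeddingMode `"C"` (frozen embedding vectors) or `"V"`
#'   (trained with the network).
#' @param seed master seed.
#' @return a list of class `CmicConfig`.
#' @export
cmicConfig <- function(n = 1000L, dim = 20L, hidden = 256L, epochs = 2L,
                       lr = 1e-4, batch = 32L, dropout = 0.5,
                       weightDecay = 0.01, decayForm = c("norm", "squared"),
                       lrSchedule = c("constant", "onecycle"),
                       kmin = 4L, kmax = 12L, window = 10L, minCount = 1L,
                       embeddingMode = c("C", "V"), seed = 1L) {
  decayForm <- match.arg(decayForm)
  lrSchedule <- match.arg(lrSchedule)
  embeddingMode <- match.arg(embeddingMode)
  structure(list(n = as.integer(n), dim = as.integer(dim),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, batch = as.integer(batch), dropout = dropout,
                 weightDecay = weightDecay, decayForm = decayForm,
                 lrSchedule = lrSchedule,
                 kmin = as.integer(kmin), kmax = as.integer(kmax),
                 window = as.integer(window), minCount = as.integer(minCount),
                 embeddingMode = embeddingMode, seed = as.integer(seed)),
            class = "CmicConfig")
}

.glorot <- function(nr, nc, scale = 1) {
  lim <- sqrt(6 / (nr + nc)) / scale
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# input projections are scaled by the typical input coordinate magnitude
# so the gate pre-activations start in the responsive region of the
# sigmoid/tanh regardless of the embedding vector norms
.initCell <- function(H, D, inputScale = 1) {
  list(Wr = .glorot(H, D, inputScale), Ur = .glorot(H, H), br = numeric(H),
       Wz = .glorot(H, D, inputScale), Uz = .glorot(H, H), bz = numeric(H),
       Wh = .glorot(H, D, inputScale), Uh = .glorot(H, H), bh = numeric(H))
}

#' Initialize an untrained BiGRU model
#'
#' Glorot-uniform weight matrices (the input projections additionally
#' scaled by the embedding table's typical coordinate magnitude so the
#' gates start in their responsive region), zero initial hidden states,
#' and a head mapping the 2H-dimensional concatenated state to one logit.
#' The update-gate bias starts at `updateGateBias` (positive values bias
#' the recurrence toward retaining memory over long sentences, the GRU
#' analogue of initializing an LSTM forget gate to 1); the head bias can
#' be set to the log-odds of the class prior via `priorLogOdds`.
#'
#' @param embedding an [EmbeddingTable-class].
#' @param hidden hidden dimension H.
#' @param embeddingMode `"C"` or `"V"`.
#' @param seed RNG seed for the initialization.
#' @param updateGateBias initial value of both update-gate biases
#'   (default 1).
#' @param priorLogOdds initial head bias (default 0; [trainCmic()] sets
#'   it to the training-set log-odds).
#' @param config optional `CmicConfig` stored on the model.
#' @return a [GruModel-class].
#' @export
initGruModel <- function(embedding, hidden = 256L,
                         embeddingMode = c("C", "V"), seed = 1L,
                         updateGateBias = 1, priorLogOdds = 0,
                         config = NULL) {
  embeddingMode <- match.arg(embeddingMode)
  H <- as.integer(hidden)
  D <- embeddingDim(embedding)
  inputScale <- embedding@params$input_scale
  if (is.null(inputScale) || !is.finite(inputScale) || inputScale <= 0) {
    v <- embedding@vectors
    inputScale <- max(sqrt(mean(v^2)), 1e-8)
  }
  inputScale <- max(inputScale, 1)
  set.seed(seed)
  lim <- sqrt(6 / (2 * H + 1))
  fwd <- .initCell(H, D, inputScale)
  bwd <- .initCell(H, D, inputScale)
  fwd$bz[] <- updateGateBias
  bwd$bz[] <- updateGateBias
  methods::new("GruModel",
               forward = fwd, backward = bwd,
               headWeights = stats::runif(2L * H, -lim, lim),
               headBias = priorLogOdds,
               embedding = embedding, embeddingMode = embeddingMode,
               config = if (is.null(config)) list() else unclass(config))
}

#' One GRU step
#'
#' Computes the reset gate `r = sigmoid(Wr x + Ur h + br)`, the update
#' gate `z = sigmoid(Wz x + Uz h + bz)`, the candidate activation
#' `hc = tanh(Wh x + Uh (r * h) + bh)` and returns the affine combination
#' `h' = z * h + (1 - z) * hc`.
#'
#' @param x input vector (length D).
#' @param hPrev previous hidden state (length H).
#' @param cell list of cell weights (`Wr, Ur, br, Wz, Uz, bz, Wh, Uh, bh`).
#' @return the new hidden state (length H).
#' @export
gruStep <- function(x, hPrev, cell) {
  if (length(x) != ncol(cell$Wr) || length(hPrev) != nrow(cell$Wr))
    stop("shape mismatch between x/hPrev and cell weights")
  sig <- function(a) 1 / (1 + exp(-a))
  r <- sig(drop(cell$Wr %*% x) + drop(cell$Ur %*% hPrev) + cell$br)
  z <- sig(drop(cell$Wz %*% x) + drop(cell$Uz %*% hPrev) + cell$bz)
  hc <- tanh(drop(cell$Wh %*% x) + drop(cell$Uh %*% (r * hPrev)) + cell$bh)
  z * hPrev + (1 - z) * hc
}

#' Bidirectional GRU forward pass
#'
#' Runs the forward cell over `t = 1..T` and the backward cell over the
#' reversed input, both from zero initial states, and concatenates the
#' two final hidden states.
#'
#' @param x numeric matrix of input vectors, one row per time step
#'   (T x D), or a vector for T = 1.
#' @param model a [GruModel-class].
#' @return numeric vector of length 2H.
#' @export
bigruForward <- function(x, model) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (nrow(x) < 1L) stop("input sequence is empty")
  as.numeric(cpp_bigru_forward(t(x), model@forward, model@backward))
}

#' Score one k-mer sentence
#'
#' Embeds each token, runs the BiGRU, and applies the linear head and
#' sigmoid. Dropout is disabled at inference. The value is the predicted
#' probability that the source sequence is unmethylated.
#'
#' @param tokens character vector of k-mer tokens.
#' @param model a [GruModel-class].
#' @param oov out-of-vocabulary policy for the embedding lookup.
#' @return probability in (0, 1).
#' @export
predictSentence <- function(tokens, model, oov = c("zero", "strict")) {
  x <- lookupEmbedding(model@embedding, tokens, oov = match.arg(oov))
  u <- bigruForward(x, model)
  drop(1 / (1 + exp(-(sum(model@headWeights * u) + model@headBias))))
}

# score a list of token-id sentences with the compiled path
.predictIds <- function(idsList, model) {
  cpp_predict(idsList, model@embedding@vectors, model@forward,
              model@backward, model@headWeights, model@headBias)
}

#' Predict the methylation class of CGI sequences
#'
#' Each sequence is augmented into 2N cognate sentences (forward and
#' reverse-complement splits), every sentence is scored, and sentence
#' probabilities are averaged into one per-CGI probability. The label is
#' `unmethylated` (1) iff the aggregated probability is strictly greater
#' than 0.5; a tie at exactly 0.5 is called methylated.
#'
#' @param seqs a `DNAStringSet` or named character vector.
#' @param model a [GruModel-class].
#' @param cfg a [segmentationConfig()]; defaults to the model's stored
#'   config when available.
#' @param sentenceIds optional precomputed token-id sentences (list per
#'   CGI) to reuse existing splits.
#' @return data.frame with columns `id`, `prob`, `label`, plus the
#'   per-sentence probabilities as an attribute `"sentence_probs"`.
#' @export
predictCgi <- function(seqs, model, cfg = NULL, sentenceIds = NULL) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(cfg)) {
    cc <- model@config
    cfg <- segmentationConfig(
      kmin = if (is.null(cc$kmin)) 4L else cc$kmin,
      kmax = if (is.null(cc$kmax)) 12L else cc$kmax,
      nReplicates = if (is.null(cc$n)) 1000L else cc$n,
      seed = if (is.null(cc$seed)) 1L else cc$seed)
  }
  vocab <- rownames(model@embedding@vectors)
  perCgi <- lapply(names(seqs), function(id) {
    ids <- if (!is.null(sentenceIds)) sentenceIds[[id]]
           else .sentenceIds(augmentSequence(seqs[[id]], id = id,
                                             cfg = cfg)@sentences, vocab)
    .predictIds(ids, model)
  })
  names(perCgi) <- names(seqs)
  prob <- vapply(perCgi, mean, numeric(1))
  out <- data.frame(id = names(seqs), prob = unname(prob),
                    label = as.integer(unname(prob) > 0.5),
                    stringsAsFactors = FALSE)
  attr(out, "sentence_probs") <- perCgi
  out
}

#' Training loss: cross-entropy plus weight decay
#'
#' `L(w) = E(yhat, y) + alpha * ||w||_2` with
#' `E = -sum(y * log(yhat) + (1 - y) * log(1 - yhat))`. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` before the logs. `form = "squared"`
#' penalizes the squared norm instead.
#'
#' @param yHat predicted probabilities.
#' @param y binary labels (same length).
#' @param weights numeric vector of decayed parameters (optional).
#' @param alpha decay coefficient.
#' @param form `"norm"` or `"squared"`.
#' @return scalar loss.
#' @export
cmicLoss <- function(yHat, y, weights = numeric(0), alpha = 0,
                     form = c("norm", "squared")) {
  form <- match.arg(form)
  if (length(yHat) != length(y)) stop("yHat and y must have equal length")
  p <- pmin(pmax(yHat, 1e-7), 1 - 1e-7)
  ce <- -sum(y * log(p) + (1 - y) * log(1 - p))
  nrm <- sqrt(sum(weights^2))
  ce + if (form == "norm") alpha * nrm else alpha * nrm^2
}

# flatten sentences of a KmerCorpus into token ids for a model vocabulary
.corpusIds <- function(corpus, vocab) .sentenceIds(corpus@sentences, vocab)

#' Train the BiGRU classifier
#'
#' Minimizes the cross-entropy plus weight-decay loss with Adam over
#' mini-batches of cognate sentences. Dropout (rate `config$dropout`) is
#' applied to the concatenated BiGRU output during training only. With
#' `embeddingMode = "C"` the embedding table is left untouched; with
#' `"V"` it is updated alongside the network weights.
#'
#' @param corpus a [KmerCorpus-class] with labels (0/1) for every sentence.
#' @param embedding an [EmbeddingTable-class] used to initialize the
#'   embedding layer.
#' @param config a [cmicConfig()].
#' @param model optional pre-initialized [GruModel-class] to continue from.
#' @return a trained [GruModel-class]; the per-epoch mean data loss is in
#'   `model@config$loss_trace`.
#' @export
trainCmic <- function(corpus, embedding = NULL, config = cmicConfig(),
                      model = NULL) {
  info <- corpus@info
  if (anyNA(info$label)) stop("every training sentence needs a 0/1 label")
  if (length(unique(info$label)) < 2L)
    warning("training data contains a single class")
  if (is.null(model)) {
    if (is.null(embedding)) stop("provide an embedding table or a model")
    n1 <- sum(info$label == 1L); n0 <- sum(info$label == 0L)
    prior <- if (n1 > 0L && n0 > 0L) log(n1 / n0) else 0
    model <- initGruModel(embedding, hidden = config$hidden,
                          embeddingMode = config$embeddingMode,
                          seed = config$seed, priorLogOdds = prior,
                          config = config)
  }
  vocab <- rownames(model@embedding@vectors)
  ids <- .corpusIds(corpus, vocab)
  res <- cpp_train(ids, as.integer(info$label), model@embedding@vectors,
                   model@forward, model@backward, model@headWeights,
                   model@headBias, config$lr, config$epochs, config$batch,
                   config$dropout, config$weightDecay,
                   if (config$decayForm == "norm") 0L else 1L,
                   config$embeddingMode == "V", config$seed,
                   if (identical(config$lrSchedule, "onecycle")) 1L else 0L)
  emb <- model@embedding
  if (config$embeddingMode == "V") {
    v <- res$E
    rownames(v) <- vocab
    emb <- methods::new("EmbeddingTable", vectors = v, params = emb@params)
  }
  cfg <- unclass(config)
  cfg$loss_trace <- as.numeric(res$epoch_loss)
  methods::new("GruModel", forward = res$fwd, backward = res$bwd,
               headWeights = as.numeric(res$hw), headBias = as.numeric(res$hb),
               embedding = emb, embeddingMode = config$embeddingMode,
               config = cfg)
}

#' Analytic loss gradients (no dropout)
#'
#' Exposes the exact loss value and its analytic gradients for a batch of
#' sentences, mainly for finite-difference verification of the
#' backpropagation.
#'
#' @param idsList list of integer token-id sentences (1-based; 0 = OOV).
#' @param labels integer labels aligned with `idsList`.
#' @param model a [GruModel-class].
#' @param alpha weight decay coefficient.
#' @param decayForm `"norm"` or `"squared"`.
#' @param trainEmbedding include embedding gradients.
#' @return list with `loss`, `fwd`, `bwd`, `hw`, `hb` (and `gE`).
#' @export
lossGradients <- function(idsList, labels, model, alpha = 0,
                          decayForm = c("norm", "squared"),
                          trainEmbedding = FALSE) {
  decayForm <- match.arg(decayForm)
  cpp_loss_grad(idsList, as.integer(labels), model@embedding@vectors,
                model@forward, model@backward, model@headWeights,
                model@headBias, alpha,
                if (decayForm == "norm") 0L else 1L, trainEmbedding)
}
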