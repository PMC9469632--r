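#' Stratified fold assignment at the CGI level
#'
#' Sequences are partitioned into K folds separately within each class,
#' so per-fold class proportions stay within one CGI of the global
#' proportions and all cognate sentences of a CGI share one fold.
#'
#' @param ids character vector of CGI ids.
#' @param labels binary labels aligned with `ids`.
#' @param K number of folds (default 3).
#' @param seed RNG seed; the assignment is deterministic given it.
#' @return named integer vector mapping id -> fold index in `0..K-1`.
#' @export
stratifiedFolds <- function(ids, labels, K = 3L, seed = 1L) {
  K <- as.integer(K)
  if (length(ids) != length(labels)) stop("ids and labels differ in length")
  tab <- table(labels)
  if (any(tab < K))
    stop(sprintf("every class needs at least K=%d members", K))
  set.seed(seed)
  fold <- integer(length(ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(K) - 1L, length(idx))
  }
  names(fold) <- ids
  fold
}

#' Classification metrics with the unmethylated class (1) as positive
#'
#' Balanced accuracy `(TPR + TNR) / 2`, F-measure (harmonic mean of
#' precision and recall), Matthews correlation coefficient, and the
#' rank-statistic AUC. Zero-denominator conventions: precision/recall
#' -> 0, MCC -> 0; AUC is `NA` when `yTrue` has a single class.
#'
#' @param yTrue,yPred binary vectors (0/1).
#' @param probs optional probabilities for the AUC.
#' @return one-row data.frame: `balanced_accuracy`, `f_measure`, `mcc`,
#'   `auc`.
#' @export
computeMetrics <- function(yTrue, yPred, probs = NULL) {
  if (!length(yTrue) || length(yTrue) != length(yPred))
    stop("yTrue and yPred must be non-empty and aligned")
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  tn <- sum(yTrue == 0 & yPred == 0)
  fn <- sum(yTrue == 1 & yPred == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  auc <- NA_real_
  if (!is.null(probs) && length(unique(yTrue)) == 2L) {
    r <- rank(probs)
    n1 <- sum(yTrue == 1); n0 <- sum(yTrue == 0)
    auc <- (sum(r[yTrue == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  data.frame(balanced_accuracy = (tpr + tnr) / 2, f_measure = f,
             mcc = mcc, auc = auc)
}

.subsetCorpus <- function(corpus, ids) {
  keep <- corpus@info$source_id %in% ids
  methods::new("KmerCorpus", sentences = corpus@sentences[keep],
               info = corpus@info[keep, , drop = FALSE])
}

.seqsAndLabels <- function(seqs, labels) {
  if (methods::is(seqs, "DNAStringSet")) {
    if (is.null(labels)) {
      mc <- S4Vectors::mcols(seqs)
      if (!is.null(mc) && "label" %in% colnames(mc)) labels <- mc$label
    }
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(labels)) stop("labels are required")
  list(seqs = seqs, labels = as.integer(labels))
}

# build the embedding table for a given scheme over (already generated)
# classification sentences and/or the raw sequences
.schemeEmbedding <- function(scheme, classCorpus, seqs, segCfg, config,
                             embedSeed) {
  scheme <- match.arg(scheme, c("splitDNA2vec", "splitDNA2vec-sh",
                                "dna2vec", "dna2vec-N1000"))
  corp <- switch(scheme,
    "splitDNA2vec" = ,
    "splitDNA2vec-sh" = classCorpus,
    "dna2vec" = buildCorpus(seqs,
      segmentationConfig(segCfg$kmin, segCfg$kmax, 1L, segCfg$seed),
      mode = "overlap"),
    "dna2vec-N1000" = buildCorpus(seqs, segCfg, mode = "overlap"))
  emb <- trainEmbeddings(corp, dim = config$dim, window = config$window,
                         minCount = config$minCount, seed = embedSeed)
  if (scheme == "splitDNA2vec-sh") emb <- shuffleEmbedding(emb, seed = embedSeed)
  emb
}

#' K-fold stratified cross-validation of the full pipeline
#'
#' Generates the 2N cognate sentences of every CGI once, trains the
#' embedding table transductively (unsupervised, over all sequences),
#' then for each fold trains the BiGRU on the training folds' sentences
#' and evaluates on the held-out fold at both the per-sentence and the
#' per-CGI level (mean sentence probability, threshold 0.5). A built-in
#' audit asserts that no CGI id appears in both the train and test side
#' of any fold.
#'
#' @param seqs `DNAStringSet` (labels in `mcols()$label`) or named
#'   character vector.
#' @param labels binary labels (0 = methylated, 1 = unmethylated) if not
#'   carried by `seqs`.
#' @param config a [cmicConfig()].
#' @param K folds (default 3).
#' @param seed master seed (defaults to `config$seed`).
#' @param scheme embedding scheme: `"splitDNA2vec"` (default),
#'   `"splitDNA2vec-sh"`, `"dna2vec"`, or `"dna2vec-N1000"`.
#' @param embedding optional pre-trained [EmbeddingTable-class],
#'   bypassing `scheme`.
#' @param scorer optional replacement for the trained classifier, mainly
#'   for harness checks: `function(trainCorpus, testCorpus, embedding,
#'   config, seed)` returning per-test-sentence probabilities.
#' @return list of class `CmicCvResult`: `folds` (per-fold metrics at
#'   both levels), `summary` (mean and standard error over folds),
#'   `predictions` (per-CGI test predictions pooled over folds),
#'   `fold_assignment`.
#' @export
crossValidate <- function(seqs, labels = NULL, config = cmicConfig(),
                          K = 3L, seed = NULL, scheme = "splitDNA2vec",
                          embedding = NULL, scorer = NULL) {
  sl <- .seqsAndLabels(seqs, labels)
  seqs <- sl$seqs; labels <- sl$labels
  if (is.null(seed)) seed <- config$seed
  segCfg <- segmentationConfig(config$kmin, config$kmax, config$n,
                               seed = mixSeed(seed, 11L))
  classCorpus <- buildCorpus(seqs, segCfg, labels = labels)
  if (is.null(embedding))
    embedding <- .schemeEmbedding(scheme, classCorpus, seqs, segCfg, config,
                                  embedSeed = mixSeed(seed, 12L))
  vocab <- rownames(embedding@vectors)
  idsAll <- .corpusIds(classCorpus, vocab)
  fold <- stratifiedFolds(names(seqs), labels, K = K,
                          seed = mixSeed(seed, 13L))
  info <- classCorpus@info
  foldRows <- list()
  preds <- list()
  for (k in seq_len(K) - 1L) {
    testIds <- names(fold)[fold == k]
    trainIds <- names(fold)[fold != k]
    stopifnot(length(intersect(trainIds, testIds)) == 0L)
    trainMask <- info$source_id %in% trainIds
    testMask <- info$source_id %in% testIds
    if (any(trainMask & testMask)) stop("fold leakage detected")
    trainCorpus <- methods::new("KmerCorpus",
                                sentences = classCorpus@sentences[trainMask],
                                info = info[trainMask, , drop = FALSE])
    testCorpus <- methods::new("KmerCorpus",
                               sentences = classCorpus@sentences[testMask],
                               info = info[testMask, , drop = FALSE])
    foldSeed <- mixSeed(seed, 20L, k)
    if (is.null(scorer)) {
      cfgK <- config
      cfgK$seed <- foldSeed
      modelK <- trainCmic(trainCorpus, embedding = embedding, config = cfgK)
      sentProbs <- .predictIds(idsAll[testMask], modelK)
    } else {
      sentProbs <- scorer(trainCorpus, testCorpus, embedding, config,
                          foldSeed)
    }
    testInfo <- info[testMask, , drop = FALSE]
    ySent <- testInfo$label
    sentM <- computeMetrics(ySent, as.integer(sentProbs > 0.5), sentProbs)
    cgiProb <- tapply(sentProbs, testInfo$source_id, mean)
    cgiIds <- names(cgiProb)
    yCgi <- labels[match(cgiIds, names(seqs))]
    cgiM <- computeMetrics(yCgi, as.integer(cgiProb > 0.5),
                           as.numeric(cgiProb))
    foldRows[[length(foldRows) + 1L]] <-
      cbind(data.frame(fold = k, level = "per_sentence"), sentM)
    foldRows[[length(foldRows) + 1L]] <-
      cbind(data.frame(fold = k, level = "per_cgi"), cgiM)
    preds[[length(preds) + 1L]] <-
      data.frame(fold = k, id = cgiIds, prob = as.numeric(cgiProb),
                 label = as.integer(cgiProb > 0.5), true = yCgi,
                 stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, foldRows)
  metricCols <- c("balanced_accuracy", "f_measure", "mcc", "auc")
  summ <- do.call(rbind, lapply(split(folds, folds$level), function(d) {
    data.frame(level = d$level[1], metric = metricCols,
               mean = vapply(metricCols, function(m) mean(d[[m]]), numeric(1)),
               se = vapply(metricCols, function(m)
                 stats::sd(d[[m]]) / sqrt(nrow(d)), numeric(1)),
               row.names = NULL)
  }))
  structure(list(folds = folds, summary = summ,
                 predictions = do.call(rbind, preds),
                 fold_assignment = fold),
            class = "CmicCvResult")
}

#' @export
print.CmicCvResult <- function(x, ...) {
  cat("Stratified cross-validation result\n")
  s <- x$summary[x$summary$level == "per_cgi", ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  per-CGI %-17s %.3f +/- %.3f\n", s$metric[i], s$mean[i],
                s$se[i]))
  invisible(x)
}

#' Experiment drivers: parameter and scheme sweeps
#'
#' Runs one [crossValidate()] per grid point. Experiments: `"n_replicates"`
#' (`grid` a vector of N values), `"k_range"` (`grid` a data.frame with
#' columns `kmin`, `kmax`; pairs with `kmax - kmin < 1` are dropped), and
#' `"embedding_scheme"` (`grid` a data.frame with columns `scheme`,
#' `mode`; defaults to all eight scheme x C/V combinations).
#'
#' @param experiment which parameter to sweep.
#' @param grid the grid (see above); `NULL` picks a default.
#' @param seqs,labels,config,K,seed as in [crossValidate()].
#' @return data.frame with one row per grid point: grid coordinates plus
#'   per-CGI mean and standard error of each metric.
#' @export
sweepExperiment <- function(experiment = c("n_replicates", "k_range",
                                           "embedding_scheme"),
                            grid = NULL, seqs, labels = NULL,
                            config = cmicConfig(), K = 3L, seed = 1L) {
  experiment <- match.arg(experiment)
  if (experiment == "n_replicates") {
    if (is.null(grid)) grid <- c(1L, 10L, 100L, 500L, 1000L)
    pts <- data.frame(n = as.integer(grid))
  } else if (experiment == "k_range") {
    if (is.null(grid))
      grid <- expand.grid(kmin = 2:11, kmax = 3:12)
    pts <- grid[grid$kmax - grid$kmin >= 1L, , drop = FALSE]
  } else {
    if (is.null(grid))
      grid <- expand.grid(scheme = c("splitDNA2vec", "splitDNA2vec-sh",
                                     "dna2vec", "dna2vec-N1000"),
                          mode = c("C", "V"), stringsAsFactors = FALSE)
    pts <- grid
  }
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    cfg <- config
    sch <- "splitDNA2vec"
    if (experiment == "n_replicates") cfg$n <- pts$n[i]
    if (experiment == "k_range") { cfg$kmin <- pts$kmin[i]; cfg$kmax <- pts$kmax[i] }
    if (experiment == "embedding_scheme") {
      sch <- pts$scheme[i]; cfg$embeddingMode <- pts$mode[i]
    }
    cv <- crossValidate(seqs, labels, config = cfg, K = K, seed = seed,
                        scheme = sch)
    s <- cv$summary[cv$summary$level == "per_cgi", ]
    out <- pts[i, , drop = FALSE]
    for (j in seq_len(nrow(s))) {
      out[[paste0(s$metric[j], "_mean")]] <- s$mean[j]
      out[[paste0(s$metric[j], "_se")]] <- s$se[j]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Evaluate a trained model on long CGIs, binned by length
#'
#' Applies a model trained on short (<= 500 bp) sequences to longer ones,
#' reporting per-CGI metrics within length bins `[501, 600], [601, 700],
#' ..., [1001, Inf)`.
#'
#' @param model a trained [GruModel-class].
#' @param longSeqs `DNAStringSet` with `mcols()$label`, or named character
#'   vector plus `labels`.
#' @param labels binary labels if not carried by `longSeqs`.
#' @param binStarts left edges of the length bins.
#' @param cfg segmentation configuration for prediction (defaults to the
#'   model's).
#' @return data.frame with one row per bin (`bin`, `n`, metrics; `NA`
#'   metrics for empty bins).
#' @export
evaluateLong <- function(model, longSeqs, labels = NULL,
                         binStarts = c(501L, 601L, 701L, 801L, 901L, 1001L),
                         cfg = NULL) {
  sl <- .seqsAndLabels(longSeqs, labels)
  seqs <- sl$seqs; labels <- sl$labels
  pred <- if (length(seqs)) predictCgi(seqs, model, cfg = cfg) else NULL
  lens <- nchar(seqs)
  edges <- c(binStarts, Inf)
  rows <- lapply(seq_along(binStarts), function(i) {
    lab <- if (is.finite(edges[i + 1]))
      sprintf("[%d,%d]", binStarts[i], edges[i + 1] - 1L)
    else sprintf("[%d,Inf)", binStarts[i])
    inBin <- lens >= binStarts[i] & lens < edges[i + 1]
    if (!any(inBin))
      return(data.frame(bin = lab, n = 0L, balanced_accuracy = NA_real_,
                        f_measure = NA_real_, mcc = NA_real_,
                        auc = NA_real_))
    m <- computeMetrics(labels[inBin], pred$label[match(names(seqs)[inBin],
                                                        pred$id)],
                        pred$prob[match(names(seqs)[inBin], pred$id)])
    cbind(data.frame(bin = lab, n = sum(inBin)), m)
  })
  do.call(rbind, rows)
}
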