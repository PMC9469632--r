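test_that("stratified folds balance classes and are deterministic", {
  ids <- paste0("c", 1:6)
  labels <- rep(c(0, 1), 3)
  f <- stratifiedFolds(ids, labels, K = 3, seed = 1)
  for (k in 0:2) {
    expect_equal(sum(f == k & labels == 0), 1L)
    expect_equal(sum(f == k & labels == 1), 1L)
  }
  # the 150/60 imbalanced design gives folds of 50 and 20 per class
  ids2 <- paste0("g", 1:210)
  labels2 <- rep(c(0, 1), c(150, 60))
  f2 <- stratifiedFolds(ids2, labels2, K = 3, seed = 2)
  expect_true(all(table(f2[labels2 == 0]) == 50))
  expect_true(all(table(f2[labels2 == 1]) == 20))
  expect_identical(f2, stratifiedFolds(ids2, labels2, K = 3, seed = 2))
  expect_error(stratifiedFolds(paste0("x", 1:4), c(0, 0, 0, 1), K = 3),
               "at least K")
})

test_that("metrics match closed forms on constructed confusion tables", {
  perfect <- computeMetrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                            c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc, 1)
  # TP = FP = TN = FN = 1
  m <- computeMetrics(c(1, 0, 0, 1), c(1, 1, 0, 0))
  expect_equal(m$balanced_accuracy, 0.5)
  expect_equal(m$f_measure, 0.5)
  expect_equal(m$mcc, 0)
  # all predicted positive on a mixed set: MCC -> 0 by convention
  m2 <- computeMetrics(c(1, 0, 1), c(1, 1, 1))
  expect_equal(m2$mcc, 0)
  # single-class truth: AUC reported missing
  m3 <- computeMetrics(c(1, 1), c(1, 0), c(0.9, 0.1))
  expect_true(is.na(m3$auc))
})

test_that("rank AUC agrees with an independent implementation and is monotone-invariant", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- rep(c(0, 1), each = 25)
  p <- runif(50) + 0.3 * y
  ours <- computeMetrics(y, as.integer(p > 0.5), p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  trans <- computeMetrics(y, as.integer(p > 0.5), qlogis(p / 1.4))$auc
  expect_equal(ours, trans, tolerance = 1e-12)
})

test_that("the CV harness scores an oracle at 1 and a coin at 0.5", {
  set.seed(42)
  seqs <- setNames(vapply(rep(60, 12), randomDna, character(1)),
                   paste0("c", 1:12))
  labels <- rep(c(0L, 1L), each = 6)
  cfg <- cmicConfig(n = 2, dim = 4, hidden = 2, epochs = 1, kmin = 3,
                    kmax = 6, seed = 1)
  oracle <- function(trainCorpus, testCorpus, embedding, config, seed)
    as.numeric(corpusInfo(testCorpus)$label)
  cvO <- crossValidate(seqs, labels, config = cfg, K = 3, seed = 1,
                       scorer = oracle)
  sO <- cvO$summary[cvO$summary$level == "per_cgi", ]
  expect_equal(unname(sO$mean[sO$metric != "auc"]), rep(1, 3))
  coin <- function(trainCorpus, testCorpus, embedding, config, seed)
    rep(0.5, length(testCorpus))
  cvC <- crossValidate(seqs, labels, config = cfg, K = 3, seed = 1,
                       scorer = coin)
  sC <- cvC$summary[cvC$summary$level == "per_cgi", ]
  expect_equal(sC$mean[sC$metric == "balanced_accuracy"], 0.5)
})

test_that("no CGI id straddles train and test in any fold", {
  set.seed(43)
  seqs <- setNames(vapply(rep(50, 9), randomDna, character(1)),
                   paste0("c", 1:9))
  labels <- rep(c(0L, 1L, 1L), 3)
  seen <- new.env()
  spy <- function(trainCorpus, testCorpus, embedding, config, seed) {
    tr <- unique(corpusInfo(trainCorpus)$source_id)
    te <- unique(corpusInfo(testCorpus)$source_id)
    seen[[as.character(seed)]] <- length(intersect(tr, te))
    rep(0.5, length(testCorpus))
  }
  cv <- crossValidate(seqs, labels,
                      config = cmicConfig(n = 2, dim = 4, hidden = 2,
                                          epochs = 1, kmin = 3, kmax = 6),
                      K = 3, seed = 7, scorer = spy)
  expect_true(all(unlist(as.list(seen)) == 0L))
  # each CGI is tested exactly once across folds
  expect_setequal(cv$predictions$id, names(seqs))
  expect_equal(nrow(cv$predictions), 9L)
})

test_that("sweep drivers enumerate the expected grids", {
  set.seed(44)
  seqs <- setNames(vapply(rep(40, 6), randomDna, character(1)),
                   paste0("c", 1:6))
  labels <- rep(c(0L, 1L), 3)
  cfg <- cmicConfig(n = 1, dim = 4, hidden = 2, epochs = 1, kmin = 3,
                    kmax = 6, batch = 8)
  tab <- sweepExperiment("n_replicates", grid = c(1, 2), seqs, labels,
                         config = cfg, K = 3, seed = 1)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("n", "f_measure_mean", "f_measure_se") %in%
                    colnames(tab)))
  # the default k-range grid only keeps pairs with kmax - kmin >= 1
  kgrid <- expand.grid(kmin = 2:11, kmax = 3:12)
  kept <- kgrid[kgrid$kmax - kgrid$kmin >= 1, ]
  tabK <- sweepExperiment("k_range", grid = data.frame(kmin = c(3, 6, 6),
                                                       kmax = c(4, 6, 8)),
                          seqs, labels, config = cfg, K = 3, seed = 1)
  expect_equal(nrow(tabK), 2L)   # (6,6) dropped
  expect_equal(nrow(kept), 55L)
  # default embedding-scheme grid is the eight scheme x C/V combinations
  schemes <- expand.grid(scheme = c("splitDNA2vec", "splitDNA2vec-sh",
                                    "dna2vec", "dna2vec-N1000"),
                         mode = c("C", "V"), stringsAsFactors = FALSE)
  expect_equal(nrow(schemes), 8L)
})

test_that("long-CGI evaluation bins by length and reports empty bins as missing", {
  m <- tinyModel(H = 2, D = 2, vocab = c("AC", "GT", "CA", "TG"), seed = 9)
  set.seed(45)
  seqs <- setNames(c(randomDna(550), randomDna(650), randomDna(1200),
                     randomDna(560)),
                   paste0("L", 1:4))
  labels <- c(0L, 1L, 0L, 1L)
  res <- evaluateLong(m, seqs, labels,
                      cfg = segmentationConfig(2, 4, nReplicates = 2))
  expect_equal(nrow(res), 6L)
  expect_equal(res$n[res$bin == "[501,600]"], 2L)
  expect_equal(res$n[res$bin == "[601,700]"], 1L)
  expect_equal(res$n[res$bin == "[1001,Inf)"], 1L)
  expect_true(all(is.na(res$f_measure[res$n == 0])))
  expect_false(any(is.na(res$f_measure[res$n > 0])))
})
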