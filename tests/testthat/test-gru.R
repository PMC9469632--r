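test_that("zero-weight GRU step halves the previous hidden state", {
  # with all weights zero: r = z = 0.5, candidate = tanh(0) = 0,
  # so h' = 0.5 * h
  cell <- zeroCell(3, 4)
  h <- c(0.4, -0.2, 1.0)
  expect_equal(gruStep(rnorm(4), h, cell), 0.5 * h, tolerance = 1e-15)
})

test_that("zero hidden state reduces the step to its closed form", {
  set.seed(3)
  cell <- zeroCell(3, 4)
  cell$Wz <- matrix(rnorm(12), 3, 4)
  cell$Wh <- matrix(rnorm(12), 3, 4)
  x <- rnorm(4)
  expected <- (1 - 1 / (1 + exp(-drop(cell$Wz %*% x)))) *
    tanh(drop(cell$Wh %*% x))
  expect_equal(gruStep(x, numeric(3), cell), expected, tolerance = 1e-12)
})

test_that("vectorized GRU matches the scalar oracle on random instances", {
  set.seed(11)
  for (i in 1:100) {
    D <- sample(2:4, 1); H <- sample(2:3, 1)
    cell <- randomCell(H, D)
    x <- rnorm(D); h <- rnorm(H)
    expect_equal(gruStep(x, h, cell), oracleGruStep(x, h, cell),
                 tolerance = 1e-6)
  }
})

test_that("BiGRU forward matches the scalar oracle over full sequences", {
  set.seed(12)
  for (i in 1:100) {
    D <- 3; H <- 2; T <- sample(1:6, 1)
    fwd <- randomCell(H, D); bwd <- randomCell(H, D)
    X <- matrix(rnorm(T * D), T, D)
    emb <- new("EmbeddingTable",
               vectors = matrix(0, 1, D, dimnames = list("A", NULL)),
               params = list())
    m <- new("GruModel", forward = fwd, backward = bwd,
             headWeights = numeric(2 * H), headBias = 0, embedding = emb,
             embeddingMode = "C", config = list())
    expect_equal(bigruForward(X, m), oracleBigru(X, fwd, bwd),
                 tolerance = 1e-6)
  }
})

test_that("length-1 input makes both directions a single step from zero", {
  set.seed(13)
  D <- 3; H <- 2
  fwd <- randomCell(H, D); bwd <- randomCell(H, D)
  emb <- new("EmbeddingTable",
             vectors = matrix(0, 1, D, dimnames = list("A", NULL)),
             params = list())
  m <- new("GruModel", forward = fwd, backward = bwd,
           headWeights = numeric(2 * H), headBias = 0, embedding = emb,
           embeddingMode = "C", config = list())
  x <- rnorm(D)
  u <- bigruForward(x, m)
  expect_equal(u[1:H], gruStep(x, numeric(H), fwd), tolerance = 1e-12)
  expect_equal(u[(H + 1):(2 * H)], gruStep(x, numeric(H), bwd),
               tolerance = 1e-12)
})

test_that("palindromic input with shared cells gives equal final states", {
  set.seed(14)
  D <- 3; H <- 2
  cell <- randomCell(H, D)
  X <- matrix(rnorm(3 * D), 3, D)
  X <- rbind(X, X[rev(seq_len(3)), ])   # palindromic in time
  emb <- new("EmbeddingTable",
             vectors = matrix(0, 1, D, dimnames = list("A", NULL)),
             params = list())
  m <- new("GruModel", forward = cell, backward = cell,
           headWeights = numeric(2 * H), headBias = 0, embedding = emb,
           embeddingMode = "C", config = list())
  u <- bigruForward(X, m)
  expect_equal(u[1:H], u[(H + 1):(2 * H)], tolerance = 1e-12)
})

test_that("hidden state stays between previous state and candidate", {
  set.seed(15)
  for (i in 1:50) {
    cell <- randomCell(3, 3)
    x <- rnorm(3); h <- rnorm(3)
    sig <- function(a) 1 / (1 + exp(-a))
    r <- sig(drop(cell$Wr %*% x + cell$Ur %*% h) + cell$br)
    hc <- tanh(drop(cell$Wh %*% x + cell$Uh %*% (r * h)) + cell$bh)
    hNew <- gruStep(x, h, cell)
    lo <- pmin(h, hc) - 1e-12
    hi <- pmax(h, hc) + 1e-12
    expect_true(all(hNew >= lo & hNew <= hi))
  }
})

test_that("zero head gives probability one half, any head keeps (0,1)", {
  m <- tinyModel()
  m@headWeights[] <- 0; m@headBias <- 0
  expect_equal(predictSentence(c("AA", "AB"), m), 0.5)
  m2 <- tinyModel(seed = 7)
  p <- predictSentence(c("AA", "AB", "BA"), m2)
  expect_true(p > 0 && p < 1)
  expect_identical(p, predictSentence(c("AA", "AB", "BA"), m2))
})

test_that("per-CGI aggregation averages sentences and breaks ties to methylated", {
  m <- tinyModel(vocab = c("AA", "AC", "CA", "GT", "TG", "TT"))
  m@headWeights[] <- 0; m@headBias <- 0
  res <- predictCgi(c(x = "AAACAA"), m,
                    cfg = segmentationConfig(2, 2, nReplicates = 2))
  expect_equal(res$prob, 0.5)
  expect_equal(res$label, 0L)     # strict "> 0.5" rule
  expect_length(attr(res, "sentence_probs")$x, 4L)  # 2N with N = 2
})

test_that("cross-entropy loss closed forms hold", {
  M <- 8
  expect_equal(cmicLoss(rep(0.5, M), rep(c(0, 1), M / 2)), M * log(2))
  # perfect predictions at the clip boundary: loss ~ M * log(1/(1-eps)) ~ 0
  expect_lt(cmicLoss(rep(1, 4), rep(1, 4)), 1e-5)
  # decay term is alpha * ||w||_2 on a hand-set parameter vector
  expect_equal(cmicLoss(0.5, 1, weights = c(3, 0, 0), alpha = 0.01),
               log(2) + 0.03)
  expect_equal(cmicLoss(0.5, 1, weights = c(3, 0), alpha = 0.01,
                        form = "squared"), log(2) + 0.09)
  expect_error(cmicLoss(c(0.5, 0.5), 1), "equal length")
})

test_that("analytic gradients match central finite differences", {
  model <- tinyModel(H = 2, D = 2, seed = 5)
  ids <- list(c(1L, 2L, 3L), c(3L, 1L))
  labs <- c(1L, 0L)
  for (form in c("norm", "squared")) {
    g <- lossGradients(ids, labs, model, alpha = 0.01, decayForm = form,
                       trainEmbedding = TRUE)
    lossAt <- function(m) lossGradients(ids, labs, m, alpha = 0.01,
                                        decayForm = form,
                                        trainEmbedding = TRUE)$loss
    eps <- 1e-6
    checkBlock <- function(getW, setW, gBlock) {
      W <- getW(model)
      for (i in seq_along(W)) {
        mp <- setW(model, i, W[i] + eps)
        mm <- setW(model, i, W[i] - eps)
        num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
        expect_lt(abs(num - gBlock[i]) /
                    max(1e-8, abs(num) + abs(gBlock[i])), 1e-4)
      }
    }
    for (side in c("forward", "backward")) {
      gs <- if (side == "forward") g$fwd else g$bwd
      for (w in c("Wr", "Ur", "br", "Wz", "Uz", "bz", "Wh", "Uh", "bh")) {
        checkBlock(function(m) slot(m, side)[[w]],
                   function(m, i, v) { slot(m, side)[[w]][i] <- v; m },
                   gs[[w]])
      }
    }
    checkBlock(function(m) m@headWeights,
               function(m, i, v) { m@headWeights[i] <- v; m }, g$hw)
    checkBlock(function(m) m@headBias,
               function(m, i, v) { m@headBias <- v; m }, g$hb)
    checkBlock(function(m) m@embedding@vectors,
               function(m, i, v) { m@embedding@vectors[i] <- v; m }, g$gE)
  }
})

test_that("training descends on a separable toy problem", {
  vocab <- c("AAAA", "GGGG")
  set.seed(1)
  V <- matrix(rnorm(2 * 4, sd = 0.5), 2, 4, dimnames = list(vocab, NULL))
  emb <- new("EmbeddingTable", vectors = V, params = list())
  sent <- c(rep(list(rep("AAAA", 3)), 60), rep(list(rep("GGGG", 3)), 60))
  info <- data.frame(source_id = rep(c("a", "b"), each = 60),
                     origin = "forward", replicate = 0L,
                     label = rep(c(0L, 1L), each = 60))
  corpus <- new("KmerCorpus", sentences = sent, info = info)
  cfg <- cmicConfig(n = 1, dim = 4, hidden = 4, epochs = 2, lr = 0.02,
                    batch = 8, dropout = 0, weightDecay = 0, seed = 2)
  m <- trainCmic(corpus, embedding = emb, config = cfg)
  trace <- m@config$loss_trace
  expect_length(trace, 2L)
  expect_lt(trace[2], trace[1])
  expect_lt(predictSentence(rep("AAAA", 3), m), 0.5)
  expect_gt(predictSentence(rep("GGGG", 3), m), 0.5)
})

test_that("frozen embeddings stay bit-identical; trainable ones move", {
  vocab <- c("AAAA", "GGGG", "CCCC")
  set.seed(4)
  V <- matrix(rnorm(3 * 4, sd = 0.5), 3, 4, dimnames = list(vocab, NULL))
  emb <- new("EmbeddingTable", vectors = V, params = list())
  sent <- c(rep(list(c("AAAA", "CCCC")), 30), rep(list(c("GGGG", "CCCC")), 30))
  info <- data.frame(source_id = rep(c("a", "b"), each = 30),
                     origin = "forward", replicate = 0L,
                     label = rep(c(0L, 1L), each = 30))
  corpus <- new("KmerCorpus", sentences = sent, info = info)
  base <- cmicConfig(n = 1, dim = 4, hidden = 4, epochs = 1, lr = 0.01,
                     batch = 8, dropout = 0, seed = 3)
  base$embeddingMode <- "C"
  mC <- trainCmic(corpus, embedding = emb, config = base)
  expect_identical(embeddingVectors(mC@embedding), V)
  base$embeddingMode <- "V"
  mV <- trainCmic(corpus, embedding = emb, config = base)
  expect_false(identical(embeddingVectors(mV@embedding), V))
})

test_that("training is reproducible for a fixed seed", {
  vocab <- c("AAAA", "GGGG")
  set.seed(6)
  V <- matrix(rnorm(2 * 4, sd = 0.5), 2, 4, dimnames = list(vocab, NULL))
  emb <- new("EmbeddingTable", vectors = V, params = list())
  sent <- c(rep(list("AAAA"), 20), rep(list("GGGG"), 20))
  info <- data.frame(source_id = rep(c("a", "b"), each = 20),
                     origin = "forward", replicate = 0L,
                     label = rep(c(0L, 1L), each = 20))
  corpus <- new("KmerCorpus", sentences = sent, info = info)
  cfg <- cmicConfig(n = 1, dim = 4, hidden = 3, epochs = 2, lr = 0.01,
                    batch = 4, dropout = 0.5, seed = 10)
  m1 <- trainCmic(corpus, embedding = emb, config = cfg)
  m2 <- trainCmic(corpus, embedding = emb, config = cfg)
  expect_identical(m1@forward, m2@forward)
  expect_identical(m1@headWeights, m2@headWeights)
})

test_that("single-class training data triggers a warning", {
  vocab <- "AAAA"
  emb <- new("EmbeddingTable",
             vectors = matrix(0.1, 1, 2, dimnames = list(vocab, NULL)),
             params = list())
  corpus <- new("KmerCorpus", sentences = rep(list("AAAA"), 4),
                info = data.frame(source_id = rep("a", 4),
                                  origin = "forward",
                                  replicate = 0L, label = 0L))
  expect_warning(
    trainCmic(corpus, embedding = emb,
              config = cmicConfig(n = 1, dim = 2, hidden = 2, epochs = 1,
                                  batch = 2, dropout = 0)),
    "single class")
})

test_that("model checkpoints round-trip bit-exactly", {
  m <- tinyModel(seed = 21)
  f <- tempfile(fileext = ".rds")
  saveCmicModel(m, f)
  back <- loadCmicModel(f)
  expect_identical(back@forward, m@forward)
  expect_identical(back@backward, m@backward)
  expect_identical(back@headWeights, m@headWeights)
  expect_identical(embeddingVectors(back@embedding),
                   embeddingVectors(m@embedding))
})
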