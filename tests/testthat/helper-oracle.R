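# Scalar (component-by-component) oracle for the GRU recurrence, written
# with explicit loops and sums, independent of the vectorized/compiled
# implementation it is used to verify.

oracleSigmoid <- function(a) 1 / (1 + exp(-a))

oracleGruStep <- function(x, hPrev, cell) {
  H <- length(hPrev)
  D <- length(x)
  r <- z <- hc <- hNew <- numeric(H)
  for (i in seq_len(H)) {
    ar <- cell$br[i]
    az <- cell$bz[i]
    for (j in seq_len(D)) {
      ar <- ar + cell$Wr[i, j] * x[j]
      az <- az + cell$Wz[i, j] * x[j]
    }
    for (j in seq_len(H)) {
      ar <- ar + cell$Ur[i, j] * hPrev[j]
      az <- az + cell$Uz[i, j] * hPrev[j]
    }
    r[i] <- oracleSigmoid(ar)
    z[i] <- oracleSigmoid(az)
  }
  for (i in seq_len(H)) {
    ah <- cell$bh[i]
    for (j in seq_len(D)) ah <- ah + cell$Wh[i, j] * x[j]
    for (j in seq_len(H)) ah <- ah + cell$Uh[i, j] * (r[j] * hPrev[j])
    hc[i] <- tanh(ah)
    hNew[i] <- z[i] * hPrev[i] + (1 - z[i]) * hc[i]
  }
  hNew
}

oracleGruRun <- function(X, cell) {
  # X: T x D matrix, rows are time steps
  h <- numeric(nrow(cell$Wr))
  for (t in seq_len(nrow(X))) h <- oracleGruStep(X[t, ], h, cell)
  h
}

oracleBigru <- function(X, fwdCell, bwdCell) {
  c(oracleGruRun(X, fwdCell),
    oracleGruRun(X[rev(seq_len(nrow(X))), , drop = FALSE], bwdCell))
}

randomCell <- function(H, D) {
  list(Wr = matrix(rnorm(H * D, sd = 0.5), H, D),
       Ur = matrix(rnorm(H * H, sd = 0.5), H, H),
       br = rnorm(H, sd = 0.3),
       Wz = matrix(rnorm(H * D, sd = 0.5), H, D),
       Uz = matrix(rnorm(H * H, sd = 0.5), H, H),
       bz = rnorm(H, sd = 0.3),
       Wh = matrix(rnorm(H * D, sd = 0.5), H, D),
       Uh = matrix(rnorm(H * H, sd = 0.5), H, H),
       bh = rnorm(H, sd = 0.3))
}

zeroCell <- function(H, D) {
  list(Wr = matrix(0, H, D), Ur = matrix(0, H, H), br = numeric(H),
       Wz = matrix(0, H, D), Uz = matrix(0, H, H), bz = numeric(H),
       Wh = matrix(0, H, D), Uh = matrix(0, H, H), bh = numeric(H))
}

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny model helper for gradient / training tests
tinyModel <- function(H = 2, D = 2, vocab = c("AA", "AB", "BA"), seed = 5) {
  set.seed(seed)
  V <- matrix(rnorm(length(vocab) * D, sd = 0.5), length(vocab), D,
              dimnames = list(vocab, NULL))
  emb <- new("EmbeddingTable", vectors = V, params = list())
  initGruModel(emb, hidden = H, seed = seed)
}
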