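#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

# deterministic substream seeds: mixes a master seed with stream indices
# so per-(sequence, origin, replicate) draws do not depend on iteration
# order. Kept below 2^31 - 1 (R's integer range).
mixSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}

# numeric id for a sequence id string, for seed mixing
.idHash <- function(id) {
  v <- utf8ToInt(id)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  h
}

#' Normalize a raw DNA sequence string
#'
#' Uppercases and validates the alphabet; anything outside `A,C,G,T,N`
#' is rejected with the 1-based position of the first offending character.
#'
#' @param raw a single character string.
#' @return the normalized (uppercase) sequence string.
#' @examples
#' normalizeSequence("acgt")
#' @export
normalizeSequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("sequence must be a single non-empty string")
  s <- toupper(raw)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(s, bad, bad), bad))
  s
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` is its own complement.
#'
#' @param seq a normalized sequence string (see [normalizeSequence()]).
#' @return the reverse-complemented string.
#' @examples
#' reverseComplementDna("AAAC") # "GTTT"
#' @export
reverseComplementDna <- function(seq) {
  seq <- normalizeSequence(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Segmentation configuration
#'
#' Parameters of the variable-length k-mer segmentation: token lengths are
#' drawn i.i.d. from the discrete uniform distribution on
#' `{kmin, ..., kmax}`, and each sequence is split `nReplicates` (N) times
#' per strand, giving 2N cognate sentences.
#'
#' @param kmin,kmax bounds of the token length distribution (defaults 4, 12).
#' @param nReplicates N, the number of splits per strand (default 1000).
#' @param seed master seed for the per-replicate substreams.
#' @return a list of class `SegmentationConfig`.
#' @export
segmentationConfig <- function(kmin = 4L, kmax = 12L, nReplicates = 1000L,
                               seed = 1L) {
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  nReplicates <- as.integer(nReplicates)
  if (kmin < 1L) stop("kmin must be >= 1")
  if (kmax < kmin) stop("kmax must be >= kmin")
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  structure(list(kmin = kmin, kmax = kmax, nReplicates = nReplicates,
                 seed = as.integer(seed)),
            class = "SegmentationConfig")
}

# one non-overlapping split; assumes seq normalized and RNG already seeded
.splitOnce <- function(seq, kmin, kmax) {
  L <- nchar(seq)
  m <- ceiling(L / kmin)
  lens <- if (kmin == kmax) rep(kmin, m)
          else sample.int(kmax - kmin + 1L, m, replace = TRUE) + kmin - 1L
  cs <- cumsum(lens)
  last <- which(cs >= L)[1L]
  starts <- c(1L, cs[seq_len(last - 1L)] + 1L)
  ends <- pmin(cs[seq_len(last)], L)
  substring(seq, starts, ends)
}

#' Split a sequence into non-overlapping variable-length k-mers
#'
#' Left-to-right greedy split: each token length is drawn i.i.d. from the
#' discrete uniform on `{kmin, ..., kmax}`; the concatenation of the tokens
#' reconstructs the input exactly. When the remaining suffix is shorter
#' than the drawn length it is emitted whole as the final token, so the
#' final token may be shorter than `kmin`.
#'
#' @param seq a sequence string (normalized internally).
#' @param cfg a [segmentationConfig()].
#' @param seed optional seed overriding `cfg$seed` for this single split.
#' @return character vector of tokens.
#' @examples
#' splitVariableKmers("ACGTACGT", segmentationConfig(kmin = 2, kmax = 2))
#' @export
splitVariableKmers <- function(seq, cfg = segmentationConfig(), seed = NULL) {
  seq <- normalizeSequence(seq)
  set.seed(if (is.null(seed)) cfg$seed else seed)
  .splitOnce(seq, cfg$kmin, cfg$kmax)
}

#' Split into overlapping variable-length k-mers (sliding window, stride 1)
#'
#' One token starts at every position while at least `kmin` bases remain;
#' each token's length is drawn uniformly on `{kmin, ..., kmax}` and
#' truncated at the sequence end. This is the overlapping control scheme
#' used to compare against the non-overlapping splits.
#'
#' @inheritParams splitVariableKmers
#' @return character vector of tokens.
#' @export
splitOverlappingKmers <- function(seq, cfg = segmentationConfig(), seed = NULL) {
  seq <- normalizeSequence(seq)
  L <- nchar(seq)
  if (L < cfg$kmin)
    stop(sprintf("sequence length %d is shorter than kmin=%d", L, cfg$kmin))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  starts <- seq_len(L - cfg$kmin + 1L)
  lens <- if (cfg$kmin == cfg$kmax) rep(cfg$kmin, length(starts))
          else sample.int(cfg$kmax - cfg$kmin + 1L, length(starts),
                          replace = TRUE) + cfg$kmin - 1L
  ends <- pmin(starts + lens - 1L, L)
  substring(seq, starts, ends)
}

#' Split into fixed-length k-mers with a fixed stride
#'
#' Tokens start at positions `1, 1+stride, 1+2*stride, ...` while a full
#' k-mer fits; the classical fixed-k tokenization used by fixed-k GRU
#' classifiers.
#'
#' @param seq sequence string.
#' @param k token length (>= 1).
#' @param stride step between token starts (>= 1).
#' @return character vector of tokens.
#' @export
splitFixedKmers <- function(seq, k, stride = 1L) {
  seq <- normalizeSequence(seq)
  k <- as.integer(k); stride <- as.integer(stride)
  if (k < 1L || stride < 1L) stop("k and stride must be >= 1")
  L <- nchar(seq)
  if (L < k) stop(sprintf("sequence length %d is shorter than k=%d", L, k))
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

#' Augment one sequence into 2N cognate k-mer sentences
#'
#' Generates N independent non-overlapping splits of the sequence and N of
#' its reverse complement. All 2N sentences share the sequence's id and
#' label ("cognate" sentences). Each (origin, replicate) pair draws from
#' its own deterministic substream of `cfg$seed`, so results do not depend
#' on iteration order.
#'
#' @param seq sequence string.
#' @param id sequence identifier carried into the corpus.
#' @param label optional class label (0 = methylated, 1 = unmethylated).
#' @param cfg a [segmentationConfig()].
#' @param mode `"nonoverlap"` (default) or `"overlap"` (sliding-window
#'   control scheme).
#' @return a [KmerCorpus-class] with 2N sentences.
#' @export
augmentSequence <- function(seq, id = "seq1", label = NA_integer_,
                            cfg = segmentationConfig(),
                            mode = c("nonoverlap", "overlap")) {
  mode <- match.arg(mode)
  seq <- normalizeSequence(seq)
  rc <- reverseComplementDna(seq)
  N <- cfg$nReplicates
  idh <- .idHash(id)
  splitFun <- if (mode == "nonoverlap") {
    function(s, sd) { set.seed(sd); .splitOnce(s, cfg$kmin, cfg$kmax) }
  } else {
    function(s, sd) splitOverlappingKmers(s, cfg, seed = sd)
  }
  sent <- vector("list", 2L * N)
  for (r in seq_len(N)) {
    sent[[r]] <- splitFun(seq, mixSeed(cfg$seed, idh, 0L, r))
    sent[[N + r]] <- splitFun(rc, mixSeed(cfg$seed, idh, 1L, r))
  }
  info <- data.frame(
    source_id = id,
    origin = rep(c("forward", "reverse_complement"), each = N),
    replicate = c(seq_len(N) - 1L, seq_len(N) - 1L),
    label = as.integer(label),
    stringsAsFactors = FALSE)
  methods::new("KmerCorpus", sentences = sent, info = info)
}

#' Build a corpus over a set of sequences
#'
#' Applies [augmentSequence()] to every sequence of a `DNAStringSet`
#' (or named character vector), concatenating the resulting sentences.
#' Labels, when given, are carried through per sentence; embedding
#' training ignores them (unsupervised).
#'
#' @param seqs a `Biostrings::DNAStringSet` or named character vector.
#' @param cfg a [segmentationConfig()].
#' @param labels optional integer vector (0/1) aligned with `seqs`;
#'   alternatively labels are read from `S4Vectors::mcols(seqs)$label`.
#' @param mode `"nonoverlap"` or `"overlap"`.
#' @return a [KmerCorpus-class].
#' @export
buildCorpus <- function(seqs, cfg = segmentationConfig(), labels = NULL,
                        mode = c("nonoverlap", "overlap")) {
  mode <- match.arg(mode)
  if (methods::is(seqs, "DNAStringSet")) {
    if (is.null(labels)) {
      mc <- S4Vectors::mcols(seqs)
      if (!is.null(mc) && "label" %in% colnames(mc)) labels <- mc$label
    }
    seqs <- as.character(seqs)
  }
  if (length(seqs) == 0L) stop("empty sequence set")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(labels)) labels <- rep(NA_integer_, length(seqs))
  parts <- lapply(seq_along(seqs), function(i) {
    augmentSequence(seqs[[i]], id = names(seqs)[i], label = labels[i],
                    cfg = cfg, mode = mode)
  })
  methods::new("KmerCorpus",
               sentences = do.call(c, lapply(parts, function(p) p@sentences)),
               info = do.call(rbind, lapply(parts, function(p) p@info)))
}
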