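#' Specification of a synthetic CGI-like dataset
#'
#' Defaults echo the shape of the real inheritance dataset the classifier
#' targets: 150 methylation-inheriting (class 0) and 60 methylation-losing
#' (class 1) CGIs, lengths uniform on 200..500 bp, GC content 0.65 with a
#' boosted CpG dinucleotide propensity, and three copies of a
#' class-specific 10-mer motif planted per sequence on random strands.
#'
#' @param nPerClass integer vector of length 2: sequences in class 0 and
#'   class 1.
#' @param lengthRange `[min_bp, max_bp]` of sequence lengths.
#' @param gcContent target GC fraction of the background.
#' @param cpgBoost multiplier (>= 1) applied to the propensity of G
#'   following C; the background chain is rebalanced so the overall base
#'   composition still matches `gcContent`.
#' @param motifsPerClass character vector of two disjoint motifs (class 0,
#'   class 1).
#' @param motifCopies planted copies per sequence (0 disables planting).
#' @param seed master seed.
#' @return a list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nPerClass = c(150L, 60L),
                          lengthRange = c(200L, 500L),
                          gcContent = 0.65, cpgBoost = 5,
                          motifsPerClass = c("ATATATATAT", "AATTAATTAA"),
                          motifCopies = 3L, seed = 1L) {
  stopifnot(length(nPerClass) == 2L, all(nPerClass >= 1L),
            length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
            gcContent > 0, gcContent <= 1, cpgBoost >= 1,
            length(motifsPerClass) == 2L, motifCopies >= 0L)
  if (motifsPerClass[1] == motifsPerClass[2])
    stop("class motifs must be distinct strings")
  if (any(nchar(motifsPerClass) > lengthRange[1]))
    stop("motif longer than the minimum sequence length")
  if (grepl("[^ACGT]", paste(motifsPerClass, collapse = "")))
    stop("motifs must be over {A,C,G,T}")
  structure(list(nPerClass = as.integer(nPerClass),
                 lengthRange = as.integer(lengthRange),
                 gcContent = gcContent, cpgBoost = cpgBoost,
                 motifsPerClass = motifsPerClass,
                 motifCopies = as.integer(motifCopies),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# first-order transition rows hitting a target composition exactly while
# boosting P(G | previous = C) by `boost` before rebalancing. Returns a
# 4x4 matrix (rows = previous base A,C,G,T; columns = next base).
.backgroundChain <- function(gcContent, boost) {
  p <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
         G = gcContent / 2, T = (1 - gcContent) / 2)
  if (p["C"] == 0 || boost == 1) {
    tm <- matrix(rep(p, 4), nrow = 4, byrow = TRUE)
    dimnames(tm) <- list(names(p), names(p))
    return(tm)
  }
  q <- p
  for (i in 1:200) {
    w <- q * c(1, 1, boost, 1)
    r <- w / sum(w)
    qNew <- (p - p["C"] * r) / (1 - p["C"])
    qNew <- pmax(qNew, 0)
    qNew <- qNew / sum(qNew)
    q <- (q + qNew) / 2          # damped to avoid oscillation
  }
  w <- q * c(1, 1, boost, 1)
  r <- w / sum(w)
  q <- pmax((p - p["C"] * r) / (1 - p["C"]), 0)
  q <- q / sum(q)
  tm <- rbind(A = q, C = r, G = q, T = q)
  colnames(tm) <- names(p)
  tm
}

#' Generate a CGI-like background sequence
#'
#' First-order Markov sampling whose stationary base composition matches
#' `gcContent` (P(G) + P(C) = gcContent) while the CpG dinucleotide
#' frequency is raised above the independence expectation by boosting the
#' propensity of G after C.
#'
#' @param length sequence length (>= 1).
#' @param gcContent target GC fraction.
#' @param cpgBoost CpG propensity multiplier (>= 1).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return a sequence string.
#' @export
generateBackground <- function(length, gcContent = 0.65, cpgBoost = 5,
                               seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tm <- .backgroundChain(gcContent, cpgBoost)
  bases <- colnames(tm)
  p0 <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2,
          (1 - gcContent) / 2)
  out <- integer(length)
  out[1] <- sample.int(4L, 1L, prob = p0)
  if (length > 1) {
    u <- stats::runif(length - 1L)
    cums <- t(apply(tm, 1, cumsum))
    for (i in 2:length) {
      out[i] <- findInterval(u[i - 1L], cums[out[i - 1L], ],
                             left.open = TRUE) + 1L
    }
  }
  paste(bases[out], collapse = "")
}

# place `copies` non-overlapping motif instances; returns integer starts
.placeMotifs <- function(seqLen, motifLen, copies) {
  if (copies == 0L) return(integer(0))
  if (copies * motifLen > seqLen) stop("motif copies cannot fit")
  starts <- integer(0)
  avail <- seq_len(seqLen - motifLen + 1L)
  for (i in seq_len(copies)) {
    if (!length(avail)) stop("motif copies cannot fit without overlap")
    s <- avail[sample.int(length(avail), 1L)]
    starts <- c(starts, s)
    avail <- avail[avail > s + motifLen - 1L | avail < s - motifLen + 1L]
  }
  sort(starts)
}

#' Generate a labeled synthetic dataset with a ground-truth manifest
#'
#' Background sequences per [generateBackground()], with
#' `spec$motifCopies` non-overlapping copies of the class-specific motif
#' overwritten at random positions, each on a random strand (the reverse
#' complement is planted with probability 0.5). The manifest records
#' every insertion.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `seqs` (a `DNAStringSet`, labels in `mcols()$label`)
#'   and `manifest` (data.frame: id, label, motif, position, strand).
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  set.seed(spec$seed)
  n <- sum(spec$nPerClass)
  labels <- rep(c(0L, 1L), spec$nPerClass)
  ids <- sprintf("cgi%04d", seq_len(n))
  lens <- sample(seq.int(spec$lengthRange[1], spec$lengthRange[2]), n,
                 replace = TRUE)
  seqs <- character(n)
  man <- list()
  for (i in seq_len(n)) {
    s <- generateBackground(lens[i], spec$gcContent, spec$cpgBoost)
    motif <- spec$motifsPerClass[labels[i] + 1L]
    if (spec$motifCopies > 0L) {
      starts <- .placeMotifs(lens[i], nchar(motif), spec$motifCopies)
      for (st in starts) {
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        ins <- if (strand == "+") motif else reverseComplementDna(motif)
        substr(s, st, st + nchar(motif) - 1L) <- ins
        man[[length(man) + 1L]] <- data.frame(
          id = ids[i], label = labels[i], motif = motif, position = st,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- s
  }
  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(dss)$label <- labels
  manifest <- if (length(man)) do.call(rbind, man)
              else data.frame(id = character(0), label = integer(0),
                              motif = character(0), position = integer(0),
                              strand = character(0))
  list(seqs = dss, manifest = manifest)
}

#' Generate toy WGBS count tables with analytically guaranteed labels
#'
#' For each CGI an intended class is drawn from `classMix`; FGO and
#' blastocyst read counts are then sampled inside the region of count
#' space that guarantees the intended label under the given thresholds:
#' \describe{
#'   \item{M2M}{FGO ratio >= betaM with enough reads; blastocyst likewise.}
#'   \item{M2U}{FGO methylated; blastocyst ratio < betaU.}
#'   \item{excluded_lowcov}{FGO whole read count below T.}
#'   \item{excluded_intermediate}{FGO coverage fine but ratio between
#'     betaU and betaM.}
#' }
#'
#' @param nCgi number of CGIs.
#' @param classMix named integer vector over the four intended classes
#'   summing to `nCgi`.
#' @param fgoThr,blastThr [thresholdConfig()]s.
#' @param seed RNG seed.
#' @return list with `fgo` and `blast` count data.frames and `expected`
#'   (data.frame: cgi_id, class with values M2M / M2U / excluded).
#' @export
generateCountTable <- function(nCgi = 20L,
                               classMix = c(M2M = 8L, M2U = 6L,
                                            excluded_lowcov = 3L,
                                            excluded_intermediate = 3L),
                               fgoThr = thresholdPreset("FGO"),
                               blastThr = thresholdPreset("blastocyst"),
                               seed = 1L) {
  if (sum(classMix) != nCgi) stop("classMix must sum to nCgi")
  set.seed(seed)
  intended <- sample(rep(names(classMix), classMix))
  ids <- sprintf("cgi%04d", seq_len(nCgi))

  sampleM <- function(thr) {
    total <- thr$T + sample.int(100L, 1L)
    meth <- min(total, ceiling(stats::runif(1, thr$betaM, 1) * total))
    c(total, meth)
  }
  sampleU <- function(thr) {
    total <- thr$T + sample.int(100L, 1L)
    meth <- floor(stats::runif(1, 0, thr$betaU) * total)
    if (meth / total >= thr$betaU) meth <- meth - 1L
    c(total, max(0L, meth))
  }
  sampleMid <- function(thr) {
    total <- thr$T + sample.int(100L, 1L)
    lo <- ceiling(thr$betaU * total)
    hi <- ceiling(thr$betaM * total) - 1L
    c(total, sample(lo:hi, 1L))
  }
  sampleLow <- function(thr) {
    total <- sample.int(max(1L, thr$T - 1L), 1L)
    c(total, sample.int(total + 1L, 1L) - 1L)
  }

  fgo <- matrix(0L, nCgi, 2); blast <- matrix(0L, nCgi, 2)
  for (i in seq_len(nCgi)) {
    fgo[i, ] <- switch(intended[i],
      M2M = , M2U = sampleM(fgoThr),
      excluded_lowcov = sampleLow(fgoThr),
      excluded_intermediate = sampleMid(fgoThr))
    blast[i, ] <- switch(intended[i],
      M2M = sampleM(blastThr),
      M2U = sampleU(blastThr),
      sampleM(blastThr))   # irrelevant: FGO side already excludes
  }
  expected <- ifelse(intended %in% c("M2M", "M2U"), intended, "excluded")
  list(
    fgo = data.frame(cgi_id = ids, total_reads = fgo[, 1],
                     methylated_reads = fgo[, 2], stringsAsFactors = FALSE),
    blast = data.frame(cgi_id = ids, total_reads = blast[, 1],
                       methylated_reads = blast[, 2],
                       stringsAsFactors = FALSE),
    expected = data.frame(cgi_id = ids, class = expected,
                          intended = intended, stringsAsFactors = FALSE))
}
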