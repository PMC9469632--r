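#' Threshold configuration for WGBS methylation labeling
#'
#' A CGI with fewer than `T` covering reads is excluded; otherwise it is
#' labeled M (methylated) when its methylation ratio is `>= betaM` and U
#' (unmethylated) when the ratio is `< betaU`; intermediate ratios are
#' excluded. Presets: `"FGO"` (fully grown oocyte: T = 100, betaM = 0.8,
#' betaU = 0.1) and `"blastocyst"` (maternal genome of blastocysts:
#' T = 20, betaM = 0.4, betaU = 0.1).
#'
#' @param T minimum whole read count.
#' @param betaM lower bound of the methylated ratio region.
#' @param betaU upper bound of the unmethylated ratio region.
#' @return a list of class `ThresholdConfig`.
#' @export
thresholdConfig <- function(T = 100L, betaM = 0.8, betaU = 0.1) {
  if (!(betaU >= 0 && betaU < betaM && betaM <= 1))
    stop("need 0 <= betaU < betaM <= 1")
  if (T < 0) stop("T must be non-negative")
  structure(list(T = as.integer(T), betaM = betaM, betaU = betaU),
            class = "ThresholdConfig")
}

#' @rdname thresholdConfig
#' @param preset `"FGO"` or `"blastocyst"`.
#' @export
thresholdPreset <- function(preset = c("FGO", "blastocyst")) {
  switch(match.arg(preset),
         FGO = thresholdConfig(100L, 0.8, 0.1),
         blastocyst = thresholdConfig(20L, 0.4, 0.1))
}

#' Label CGIs as M / U / excluded from read counts
#'
#' Vectorized over CGIs. The methylation ratio is
#' `methylated_reads / total_reads`.
#'
#' @param totalReads,methylatedReads non-negative integer vectors.
#' @param thr a [thresholdConfig()].
#' @return character vector in `{"M", "U", "excluded"}`.
#' @examples
#' labelCgi(150, 128, thresholdPreset("FGO")) # "M"
#' @export
labelCgi <- function(totalReads, methylatedReads, thr = thresholdPreset("FGO")) {
  if (any(totalReads < 0) || any(methylatedReads < 0))
    stop("read counts must be non-negative")
  if (any(methylatedReads > totalReads))
    stop("methylated_reads exceeds total_reads for some CGI")
  ratio <- ifelse(totalReads > 0, methylatedReads / totalReads, NA_real_)
  out <- rep("excluded", length(totalReads))
  ok <- totalReads >= thr$T
  out[ok & !is.na(ratio) & ratio >= thr$betaM] <- "M"
  out[ok & !is.na(ratio) & ratio < thr$betaU] <- "U"
  out
}

#' Derive the methylation inheritance class
#'
#' Only CGIs methylated in FGOs define the target set: a CGI that stays
#' methylated in the maternal genome of the blastocyst is M2M
#' (methylation inheritance), one that loses it is M2U (methylation
#' loss); every other combination is excluded.
#'
#' @param fgoLabel,blastLabel character vectors of `"M"/"U"/"excluded"`.
#' @return character vector in `{"M2M", "M2U", "excluded"}`.
#' @export
inheritanceClass <- function(fgoLabel, blastLabel) {
  out <- rep("excluded", length(fgoLabel))
  out[fgoLabel == "M" & blastLabel == "M"] <- "M2M"
  out[fgoLabel == "M" & blastLabel == "U"] <- "M2U"
  out
}

#' Build a labeled sequence dataset from count tables and FASTA
#'
#' Joins FGO and blastocyst count tables on CGI id, computes M2M/M2U
#' inheritance classes under the given thresholds, and attaches binary
#' labels to the sequences: M2M -> 0 (methylated), M2U -> 1
#' (unmethylated). Sequences longer than `maxLen` (boundary inclusive:
#' "at most `maxLen` bp" stay) are routed to a separate `long` set for
#' generalization analysis.
#'
#' @param fgoCounts,blastCounts data.frames with columns `cgi_id`,
#'   `total_reads`, `methylated_reads` (see [readCountTable()]).
#' @param seqs `DNAStringSet` (or named character vector) of CGI
#'   sequences; every labeled CGI id must be present.
#' @param maxLen length cutoff in bp (default 500).
#' @param fgoThr,blastThr [thresholdConfig()]s; default Table-style presets.
#' @return list with elements `short` and `long` (`DNAStringSet`s with
#'   `mcols()$label`), and `labels` (data.frame: id, fgo_label,
#'   blast_label, class).
#' @export
buildMethylationDataset <- function(fgoCounts, blastCounts, seqs,
                                    maxLen = 500L,
                                    fgoThr = thresholdPreset("FGO"),
                                    blastThr = thresholdPreset("blastocyst")) {
  if (nrow(fgoCounts) == 0L || nrow(blastCounts) == 0L)
    stop("count tables must be non-empty")
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  ids <- intersect(fgoCounts$cgi_id, blastCounts$cgi_id)
  f <- fgoCounts[match(ids, fgoCounts$cgi_id), ]
  b <- blastCounts[match(ids, blastCounts$cgi_id), ]
  fgoLab <- labelCgi(f$total_reads, f$methylated_reads, fgoThr)
  blastLab <- labelCgi(b$total_reads, b$methylated_reads, blastThr)
  cls <- inheritanceClass(fgoLab, blastLab)
  labels <- data.frame(id = ids, fgo_label = fgoLab, blast_label = blastLab,
                       class = cls, stringsAsFactors = FALSE)
  keep <- labels[labels$class != "excluded", , drop = FALSE]
  missing <- setdiff(keep$id, names(seqs))
  if (length(missing))
    stop("labeled CGI ids missing from FASTA: ",
         paste(missing, collapse = ", "))
  sel <- seqs[keep$id]
  lab <- ifelse(keep$class == "M2M", 0L, 1L)
  isLong <- Biostrings::width(sel) > maxLen
  short <- sel[!isLong]
  long <- sel[isLong]
  S4Vectors::mcols(short)$label <- lab[!isLong]
  S4Vectors::mcols(long)$label <- lab[isLong]
  list(short = short, long = long, labels = labels)
}
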