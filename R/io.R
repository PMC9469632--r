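#' Read CGI sequences from FASTA, with optional label sidecar
#'
#' @param fasta path to a FASTA file.
#' @param labels optional path to a two-column TSV `id<TAB>label`
#'   (0 = methylated, 1 = unmethylated); attached as `mcols(x)$label`.
#' @return a `Biostrings::DNAStringSet`, labels (if given) in `mcols`.
#' @export
readCgiFasta <- function(fasta, labels = NULL) {
  x <- Biostrings::readDNAStringSet(fasta)
  names(x) <- sub("\\s.*$", "", names(x))
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, header = FALSE,
                             col.names = c("id", "label"),
                             stringsAsFactors = FALSE)
    S4Vectors::mcols(x)$label <- lab$label[match(names(x), lab$id)]
  }
  x
}

#' Write a k-mer sentence corpus as word2vec text (one sentence per line)
#'
#' @param corpus a [KmerCorpus-class] or list of character vectors.
#' @param path output file.
#' @export
writeCorpus <- function(corpus, path) {
  sent <- if (methods::is(corpus, "KmerCorpus")) corpus@sentences else corpus
  writeLines(vapply(sent, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Read a corpus written by [writeCorpus()]
#'
#' @param path input file.
#' @return list of character vectors (one per sentence).
#' @export
readCorpusText <- function(path) {
  strsplit(readLines(path), " ", fixed = TRUE)
}

#' Write an embedding table in word2vec text format
#'
#' First line `V D`, then one `token v1 ... vD` line per vocabulary entry.
#'
#' @param table an [EmbeddingTable-class].
#' @param path output file.
#' @export
writeEmbeddingText <- function(table, path) {
  v <- table@vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(rownames(v)[i], paste(format(v[i, ], scientific = TRUE, digits = 17),
                                collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read an embedding table from word2vec text format
#'
#' @param path input file.
#' @return an [EmbeddingTable-class].
#' @export
readEmbeddingText <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " +")
  toks <- vapply(parts, `[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vec) <- toks
  methods::new("EmbeddingTable", vectors = vec, params = list())
}

#' Read a per-CGI methylation count table
#'
#' TSV with columns `cgi_id`, `total_reads`, `methylated_reads` (header
#' optional; detected from the first line).
#'
#' @param path input TSV.
#' @return data.frame with those three columns.
#' @export
readCountTable <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("cgi_id", first, fixed = TRUE)
  df <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) colnames(df) <- c("cgi_id", "total_reads", "methylated_reads")
  if (nrow(df) == 0L) stop("empty count table: ", path)
  df
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS archive holding every weight tensor,
#' the embedding table and the full config; `loadCmicModel(saveCmicModel(m))`
#' is bit-exact.
#'
#' @param model a [GruModel-class].
#' @param path checkpoint path.
#' @return `saveCmicModel`: the path, invisibly. `loadCmicModel`: the model.
#' @export
saveCmicModel <- function(model, path) {
  stopifnot(methods::is(model, "GruModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCmicModel
#' @export
loadCmicModel <- function(path) {
  m <- readRDS(path)
  methods::validObject(m)
  m
}
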