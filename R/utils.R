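## Internal helpers: sequence ops, RNG substreams, FASTA/FASTQ I/O, logging.

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste0(COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

random_dna <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")

is_transversion_pair <- function(a, b) {
  (a %in% PURINES & b %in% PYRIMIDINES) | (a %in% PYRIMIDINES & b %in% PURINES)
}

#' Derive a labelled RNG substream seed from a master seed
#'
#' Folds a stage label and replicate index into a master seed so that each
#' stochastic pipeline stage draws from its own reproducible stream. Kept
#' below 2^31 so the result is a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage.
#' @param index replicate index (default 0).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + index * 7907) %% 2147483629)
}

phred_to_error <- function(q) 10^(-q / 10)

qual_string_to_int <- function(q) utf8ToInt(q) - 33L

int_to_qual_string <- function(q) intToUtf8(q + 33L, multiple = FALSE)

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

## --- FASTQ / FASTA --------------------------------------------------------

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(name = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with `name`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read the first (or named) sequence of a FASTA file as a character string
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_kv <- function(kv, path) {
  utils::write.table(data.frame(key = names(kv), value = unlist(kv)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
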