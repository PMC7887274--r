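## Post-merge read filtering: minimum length and DUST low-complexity removal.

#' DUST low-complexity score of nucleotide sequences
#'
#' Windowed Morgulis-style triplet score: the maximum over 64 bp sliding
#' windows of \eqn{\sum_t c_t(c_t-1)/2 / (w-1)}, where \eqn{c_t} counts each
#' overlapping 3-mer among the window's \eqn{w} triplets. Triplets containing
#' a non-ACGT base are skipped. A 35 bp homopolymer scores 16.5; a sequence
#' with all-distinct 3-mers scores 0.
#'
#' @param seq character vector of sequences (each >= 3 bp).
#' @param window window size in bp (default 64).
#' @return Numeric vector of scores.
#' @export
dust_score <- function(seq, window = 64L) {
  if (any(nchar(seq) < 3)) stop("dust_score requires sequences of length >= 3")
  dust_score_cpp(toupper(seq), as.integer(window))
}

#' Filter reads on length and complexity
#'
#' Retains a read iff its length is at least `cfg$min_read_length` and its
#' DUST score does not exceed `cfg$dust_threshold` (a read scoring exactly
#' the threshold is kept). Reads with more than 50% N are removed as
#' degenerate and counted with the low-complexity removals. Input order is
#' preserved.
#'
#' @param reads data.frame with `name`, `seq`, `qual` (see [read_fastq()]).
#' @param cfg a [pipeline_config()].
#' @return list with `reads` (retained, same columns) and `report`
#'   (class `filter_report`: n_input, n_length_removed, n_dust_removed,
#'   n_retained).
#' @export
filter_reads <- function(reads, cfg = pipeline_config()) {
  n_input <- nrow(reads)
  if (n_input == 0) {
    rep <- filter_report(0L, 0L, 0L, 0L)
    return(list(reads = reads, report = rep))
  }
  if (!all(c("name", "seq", "qual") %in% names(reads)))
    stop("reads must have columns name, seq, qual")
  bad <- which(is.na(reads$seq) | !nzchar(reads$seq))
  if (length(bad)) stop("unreadable FASTQ record at index ", bad[1])
  len <- nchar(reads$seq)
  short <- len < cfg$min_read_length
  n_frac <- vapply(strsplit(toupper(reads$seq), "", fixed = TRUE),
                   function(ch) mean(!(ch %in% BASES)), numeric(1))
  dust <- rep(NA_real_, n_input)
  candidates <- which(!short)
  if (length(candidates))
    dust[candidates] <- dust_score(reads$seq[candidates])
  dusty <- !short & (dust > cfg$dust_threshold | n_frac > 0.5)
  keep <- !short & !dusty
  rep <- filter_report(n_input, sum(short), sum(dusty), sum(keep))
  list(reads = reads[keep, , drop = FALSE], report = rep)
}

filter_report <- function(n_input, n_length_removed, n_dust_removed, n_retained) {
  stopifnot(n_input == n_length_removed + n_dust_removed + n_retained)
  structure(list(n_input = n_input, n_length_removed = n_length_removed,
                 n_dust_removed = n_dust_removed, n_retained = n_retained),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("read filter: %d in, %d short, %d low-complexity, %d retained\n",
              x$n_input, x$n_length_removed, x$n_dust_removed, x$n_retained))
  invisible(x)
}
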