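## Desk-scale ungapped mapper, the two duplicate-removal senses used for
## degraded single-end libraries, pileup construction, and minimal SAM I/O.

aligned_read_df <- function(name = character(0), seq = character(0),
                            qual = character(0), start = integer(0),
                            strand = character(0), sample_id = character(0),
                            nm = integer(0)) {
  data.frame(name = name, seq = seq, qual = qual, start = start,
             strand = strand, sample_id = sample_id, nm = nm,
             stringsAsFactors = FALSE)
}

#' Map reads to a reference with an exact-seeded ungapped aligner
#'
#' Both orientations of each read are tried; candidate placements come from
#' exact 16-mer seeding at every query offset and are scored by full-length
#' Hamming distance. The best placement wins (ties: lowest reference start,
#' then plus strand); reads whose mismatch rate exceeds `max_mismatch_rate`
#' are dropped (counted in the `n_unmapped` attribute). Sequences and
#' qualities in the result are reference-orientated. Gapped alignment is
#' deliberately not supported: degraded-fragment variant analysis here is
#' substitution-only, and real-data users can ingest external SAM via
#' [read_sam()].
#'
#' @param reads data.frame with `name`, `seq`, `qual`.
#' @param reference reference sequence (single character string).
#' @param max_mismatch_rate maximum tolerated mismatch fraction.
#' @param sample_id sample tag stored on each alignment.
#' @param k seed length (default 16).
#' @return Aligned-read data.frame: `name`, `seq`, `qual` (reference
#'   orientation), `start` (0-based), `strand`, `sample_id`,
#'   `n_mismatches`; attribute `n_unmapped`.
#' @export
map_reads <- function(reads, reference, max_mismatch_rate = 0.1,
                      sample_id = "sample1", k = 16L) {
  if (!nzchar(reference)) stop("reference must be non-empty")
  if (nrow(reads) == 0) {
    out <- aligned_read_df()
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  hit <- map_reads_cpp(toupper(reference), toupper(reads$seq),
                       as.integer(k), max_mismatch_rate)
  keep <- hit$mapped
  seq_out <- reads$seq[keep]
  qual_out <- reads$qual[keep]
  minus <- hit$strand[keep] == "-"
  if (any(minus)) {
    seq_out[minus] <- revcomp(seq_out[minus])
    qual_out[minus] <- vapply(qual_out[minus], function(q)
      paste(rev(seq_chars(q)), collapse = ""), character(1), USE.NAMES = FALSE)
  }
  out <- data.frame(name = reads$name[keep], seq = toupper(seq_out),
                    qual = qual_out, start = hit$start[keep],
                    strand = hit$strand[keep],
                    sample_id = rep_len(sample_id, sum(keep)),
                    nm = hit$n_mismatches[keep], stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(!keep)
  out
}

normalized_sequence <- function(aln) {
  ## orientation-normalized read sequence (as sequenced, 5'->3')
  ifelse(aln$strand == "-", revcomp(aln$seq), aln$seq)
}

#' Remove exact sequence duplicates, keeping one random copy
#'
#' Reads with an identical (orientation-normalized) sequence string are
#' collapsed to a single copy chosen uniformly at random — duplicates may
#' sit at different coordinates after mapping to near-identical references,
#' so coordinate-based removal alone is insufficient. Used once per
#' replicate with a replicate-specific seed so the random choice can be
#' repeated and its sampling impact measured.
#'
#' @param aln aligned-read data.frame.
#' @param replicate_seed integer seed for the uniform choice.
#' @return Aligned-read data.frame with one read per distinct sequence.
#' @export
remove_exact_duplicates <- function(aln, replicate_seed = 1L) {
  if (nrow(aln) <= 1) return(aln)
  set.seed(substream_seed(replicate_seed, "remove_exact_duplicates"))
  key <- normalized_sequence(aln)
  groups <- split(seq_len(nrow(aln)), key)
  keep <- vapply(groups, function(ix) {
    if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
  }, integer(1))
  aln[sort(keep), , drop = FALSE]
}

#' Remove coordinate duplicates (PCR duplicates), keeping the best copy
#'
#' Reads sharing (start, strand, length) are collapsed to the copy with the
#' highest mean base quality (ties: first in input order). Deterministic and
#' idempotent. Length stands in for the outer coordinate of merged
#' single-end fragments.
#'
#' @param aln aligned-read data.frame.
#' @return Aligned-read data.frame with one read per coordinate key.
#' @export
remove_coordinate_duplicates <- function(aln) {
  if (nrow(aln) <= 1) return(aln)
  key <- paste(aln$start, aln$strand, nchar(aln$seq), sep = "|")
  meanq <- vapply(aln$qual, function(q) mean(qual_string_to_int(q)),
                  numeric(1), USE.NAMES = FALSE)
  groups <- split(seq_len(nrow(aln)), key)
  keep <- vapply(groups, function(ix) ix[which.max(meanq[ix])], integer(1))
  aln[sort(keep), , drop = FALSE]
}

#' Build a per-position pileup from aligned reads
#'
#' Tallies base counts and quality sums for every reference position from
#' the reference-orientated aligned sequences.
#'
#' @param aln aligned-read data.frame.
#' @param reference reference sequence.
#' @return Object of class `pileup`: list with `counts` (4 x L integer
#'   matrix, rows A/C/G/T), `qual_sum` (4 x L), `depth` (length-L integer),
#'   `ref` (character vector of reference bases), `mean_coverage`.
#' @export
build_pileup <- function(aln, reference) {
  L <- nchar(reference)
  counts <- matrix(0L, 4, L, dimnames = list(BASES, NULL))
  qual_sum <- matrix(0, 4, L, dimnames = list(BASES, NULL))
  if (nrow(aln) > 0) {
    lens <- nchar(aln$seq)
    if (any(aln$start + lens > L)) stop("read overruns the reference end")
    pos <- sequence(lens) - 1L + rep(aln$start, lens)      # 0-based
    base <- unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE)
    qv <- unlist(lapply(aln$qual, qual_string_to_int), use.names = FALSE)
    bi <- match(base, BASES)
    ok <- !is.na(bi)
    idx <- bi[ok] + 4L * pos[ok]                            # 1-based into 4xL
    counts[] <- tabulate(idx, nbins = 4L * L)
    qs <- rep(0, 4L * L)
    agg <- rowsum(as.numeric(qv[ok]), idx)
    qs[as.integer(rownames(agg))] <- agg[, 1]
    qual_sum[] <- qs
  }
  depth <- as.integer(colSums(counts))
  structure(list(counts = counts, qual_sum = qual_sum, depth = depth,
                 ref = seq_chars(toupper(reference)),
                 mean_coverage = sum(depth) / L),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup over %d positions, mean coverage %.1fx\n",
              length(x$depth), x$mean_coverage))
  invisible(x)
}

## --- minimal SAM ----------------------------------------------------------

#' Write aligned reads as a minimal SAM file
#'
#' Emits a header (@HD, @SQ) and one ungapped record per read: flag 0/16
#' for strand, 1-based POS, MAPQ 60, full-length match CIGAR. SEQ/QUAL are
#' reference-orientated, as SAM requires.
#'
#' @param aln aligned-read data.frame.
#' @param reference reference sequence (for the @SQ length).
#' @param ref_name reference sequence name.
#' @param path output path.
#' @export
write_sam <- function(aln, reference, ref_name = "ref", path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, nchar(reference)))
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                   aln$name, flag, ref_name, aln$start + 1L,
                   nchar(aln$seq), aln$seq, aln$qual, aln$sample_id)
  } else rec <- character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a minimal SAM file into aligned reads
#'
#' Accepts plain-text SAM with ungapped single-end records (CIGAR `<n>M` or
#' `*`); unmapped records (flag 0x4) are skipped. Soft-clips, indels and
#' spliced records are rejected — desk-scale analysis here is
#' substitution-only.
#'
#' @param path SAM file path.
#' @param sample_id sample tag to assign (default: RG tag if present).
#' @return Aligned-read data.frame (see [map_reads()]).
#' @export
read_sam <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(aligned_read_df())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(f)
  if (any(nfield < 11)) stop("malformed SAM record at line ", which(nfield < 11)[1])
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  cigar <- vapply(f, `[[`, character(1), 6)
  if (any(!grepl("^([0-9]+M|\\*)$", cigar)))
    stop("only ungapped (all-M) CIGARs are supported")
  rg <- vapply(f, function(x) {
    tag <- grep("^RG:Z:", x[-(1:11)], value = TRUE)
    if (length(tag)) sub("^RG:Z:", "", tag[1]) else NA_character_
  }, character(1))
  sid <- if (!is.null(sample_id)) sample_id else ifelse(is.na(rg), "sample1", rg)
  data.frame(name = vapply(f, `[[`, character(1), 1),
             seq = toupper(vapply(f, `[[`, character(1), 10)),
             qual = vapply(f, `[[`, character(1), 11),
             start = as.integer(vapply(f, `[[`, character(1), 4)) - 1L,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             sample_id = sid, nm = NA_integer_, stringsAsFactors = FALSE)
}
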