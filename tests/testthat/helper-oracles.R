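## Independent brute-force oracles and tiny fixture builders. These
## deliberately re-derive each quantity by the most naive route available,
## sharing no code with the implementation they check.

## DUST: exhaustive triplet counting per 64-bp window
oracle_dust <- function(seq, window = 64) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  tri <- vapply(seq_len(max(0, n - 2)), function(i)
    paste0(ch[i:(i + 2)], collapse = ""), character(1))
  valid <- !grepl("[^ACGT]", tri)
  best <- 0
  for (w0 in seq_len(max(1, n - window + 1))) {
    wend <- min(n, w0 + window - 1)
    idx <- seq(w0, wend - 2)
    idx <- idx[idx >= 1 & idx <= length(tri)]
    tt <- tri[idx][valid[idx]]
    if (length(tt) < 2) next
    cnt <- table(tt)
    score <- sum(cnt * (cnt - 1) / 2) / (length(tt) - 1)
    best <- max(best, score)
  }
  best
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## mapper: exhaustive Hamming scan over every offset and both strands
oracle_map <- function(ref, read) {
  refc <- strsplit(ref, "")[[1]]
  best <- list(mm = Inf, pos = NA, strand = NA)
  for (strand in c("+", "-")) {
    q <- if (strand == "-") oracle_revcomp(read) else read
    qc <- strsplit(q, "")[[1]]
    for (pos in 0:(nchar(ref) - nchar(read))) {
      mm <- sum(refc[(pos + 1):(pos + length(qc))] != qc)
      if (mm < best$mm ||
          (mm == best$mm && (pos < best$pos ||
                             (pos == best$pos && strand == "+" && best$strand == "-")))) {
        best <- list(mm = mm, pos = pos, strand = strand)
      }
    }
  }
  best
}

## upper binomial tail by explicit term summation
oracle_binom_tail <- function(k, n, p) {
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

## greedy window clustering, written as repeated scan over a worklist
oracle_clusters <- function(positions, span) {
  positions <- sort(unique(positions))
  out <- list()
  while (length(positions)) {
    first <- positions[1]
    members <- positions[positions - first + 1 <= span]
    positions <- setdiff(positions, members)
    if (length(members) >= 2) out[[length(out) + 1]] <- members
  }
  out
}

## per-position coverage by naive interval stabbing
oracle_stab <- function(starts, lens, L) {
  depth <- integer(L)
  for (i in seq_along(starts)) {
    for (p in starts[i]:(starts[i] + lens[i] - 1)) depth[p + 1] <- depth[p + 1] + 1
  }
  depth
}

## run-length intervals where a logical mask is TRUE (0-based half-open)
oracle_rle_intervals <- function(mask) {
  out <- NULL
  i <- 1
  while (i <= length(mask)) {
    if (mask[i]) {
      j <- i
      while (j <= length(mask) && mask[j]) j <- j + 1
      out <- rbind(out, c(i - 1, j - 1))
      i <- j
    } else i <- i + 1
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = out[, 1], end = out[, 2])
}

## toy taxonomy: root -> Eukaryota -> genusG -> (S1, S2); root -> Bacteria -> S3
toy_taxonomy <- function() {
  taxonomy_tree(data.frame(
    child = c("root", "euk", "bac", "genusG", "famF", "S1", "S2", "S3"),
    parent = c("root", "root", "root", "euk", "bac", "genusG", "genusG", "famF"),
    rank = c("root", "superkingdom", "superkingdom", "genus", "family",
             "species", "species", "species"),
    name = c("root", "Eukaryota", "Bacteria", "G", "F", "S1", "S2", "S3"),
    stringsAsFactors = FALSE))
}

make_reads <- function(seqs, qual_char = "I", prefix = "r") {
  data.frame(name = if (length(seqs)) paste0(prefix, seq_along(seqs)) else character(0),
             seq = seqs,
             qual = vapply(nchar(seqs), function(n) strrep(qual_char, n),
                           character(1)),
             stringsAsFactors = FALSE)
}

aligned <- function(seq, start, strand = "+", qual = NULL, name = NULL,
                    sample_id = "sample1") {
  n <- length(seq)
  data.frame(name = if (is.null(name)) {
               if (n) paste0("a", seq_len(n)) else character(0)
             } else name,
             seq = seq,
             qual = if (is.null(qual))
               vapply(nchar(seq), function(k) strrep("I", k), character(1))
             else qual,
             start = start,
             strand = rep_len(strand, n),
             sample_id = rep_len(sample_id, n),
             nm = rep(NA_integer_, n), stringsAsFactors = FALSE)
}

## a quick single-column pileup builder for variant-call unit tests
pileup_from_counts <- function(counts_list, ref, qual = 40) {
  L <- nchar(ref)
  counts <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  qual_sum <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (pos in names(counts_list)) {
    p <- as.integer(pos) + 1L
    for (b in names(counts_list[[pos]])) {
      counts[b, p] <- counts_list[[pos]][[b]]
      qual_sum[b, p] <- counts_list[[pos]][[b]] * qual
    }
  }
  depth <- as.integer(colSums(counts))
  structure(list(counts = counts, qual_sum = qual_sum, depth = depth,
                 ref = strsplit(toupper(ref), "")[[1]],
                 mean_coverage = sum(depth) / L),
            class = "pileup")
}
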