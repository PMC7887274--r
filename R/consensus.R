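## Iterative reference-guided reconstruction of composite organellar
## palaeogenomes: majority-rule consensus, iteration to a fixed point,
## coverage-gap reporting, and a splice hook for externally assembled
## gap patches.

#' Majority-rule consensus from a pileup
#'
#' Covered positions take the highest-count base; ties prefer the current
#' seed base when it is among the tied leaders, otherwise the
#' lexicographically smallest base (conservative, reference-stable). At
#' uncovered positions the seed base is called in `reference_fill` mode
#' (complete-genome reconstruction from a close seed) and `N` in `no_fill`
#' mode (used when mapping rates against a diverged seed are too low to
#' trust reference fill-in).
#'
#' @param pileup a [build_pileup()] result.
#' @param seed_ref seed/reference sequence the pileup was built against.
#' @param mode `"reference_fill"` or `"no_fill"`.
#' @return Consensus sequence (character string).
#' @export
majority_consensus <- function(pileup, seed_ref, mode = c("reference_fill", "no_fill")) {
  mode <- match.arg(mode)
  L <- nchar(seed_ref)
  if (length(pileup$depth) != L) stop("pileup and seed reference lengths differ")
  seedc <- seq_chars(toupper(seed_ref))
  out <- seedc
  cov <- pileup$depth > 0
  if (any(cov)) {
    cnt <- pileup$counts[, cov, drop = FALSE]
    mx <- apply(cnt, 2, max)
    pick <- character(sum(cov))
    seed_cov <- seedc[cov]
    for (j in seq_along(pick)) {
      top <- BASES[cnt[, j] == mx[j]]
      pick[j] <- if (seed_cov[j] %in% top) seed_cov[j] else top[1]
    }
    out[cov] <- pick
  }
  if (mode == "no_fill") out[!cov] <- "N"
  paste0(out, collapse = "")
}

#' Iteratively reconstruct a composite consensus genome
#'
#' Repeats map -> remove PCR duplicates -> pileup -> majority consensus
#' (reference fill), using the previous iteration's consensus as the
#' mapping reference, until the consensus can no longer be improved
#' (successive sequences identical) or `max_iter` is reached. Records the
#' number of edited positions per iteration; a run that fails to map any
#' read or to converge is returned flagged, not raised.
#'
#' @param reads read data.frame (`name`, `seq`, `qual`).
#' @param seed_ref seed genome sequence.
#' @param cfg a [pipeline_config()].
#' @param max_iter iteration cap (default 10).
#' @return Object of class `consensus_result`: `sequence`, `n_iterations`,
#'   `edits` (per-iteration changed-position counts), `gaps` (0-based
#'   half-open zero-coverage intervals of the final mapping), `low_coverage`
#'   intervals, `mean_coverage`, `converged`, `n_mapped`.
#' @export
iterate_consensus <- function(reads, seed_ref, cfg = pipeline_config(),
                              max_iter = 10L) {
  stopifnot(max_iter >= 1)
  current <- toupper(seed_ref)
  edits <- integer(0)
  converged <- FALSE
  pk <- NULL
  n_mapped <- 0L
  for (it in seq_len(max_iter)) {
    aln <- map_reads(reads, current, cfg$max_mismatch_rate)
    n_mapped <- nrow(aln)
    aln <- remove_coordinate_duplicates(aln)
    pk <- build_pileup(aln, current)
    nxt <- majority_consensus(pk, current, "reference_fill")
    edits <- c(edits, sum(seq_chars(nxt) != seq_chars(current)))
    if (nxt == current) { converged <- TRUE; break }
    current <- nxt
  }
  gaps <- coverage_gaps(pk, low_threshold = 1L)
  low <- coverage_gaps(pk, low_threshold = max(1L, as.integer(
    floor(pk$mean_coverage * cfg$var_cov_fraction))))
  structure(list(sequence = current, n_iterations = length(edits),
                 edits = edits, gaps = gaps$gap, low_coverage = low$low,
                 mean_coverage = pk$mean_coverage, converged = converged,
                 n_mapped = n_mapped, empty_mapping = n_mapped == 0L),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus: %d bp, %d iteration(s), %s, mean coverage %.1fx, %d gap(s)\n",
              nchar(x$sequence), x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              x$mean_coverage, nrow(x$gaps)))
  invisible(x)
}

#' Zero- and low-coverage intervals of a pileup
#'
#' Maximal 0-based half-open intervals where depth is zero (gaps) and where
#' depth is positive but below `low_threshold` (low coverage); disjoint,
#' sorted.
#'
#' @param pileup a [build_pileup()] result.
#' @param low_threshold depth below which covered positions count as low.
#' @return list of two data.frames `gap` and `low`, columns `start`, `end`.
#' @export
coverage_gaps <- function(pileup, low_threshold) {
  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(start = starts[r$values], end = ends[r$values])
  }
  list(gap = runs_of(pileup$depth == 0),
       low = runs_of(pileup$depth > 0 & pileup$depth < low_threshold))
}

#' Splice externally assembled patches into a consensus
#'
#' Incorporates user-provided patch sequences (e.g. de novo contigs
#' covering reported gaps) by exact flanking-anchor match: each patch gives
#' a left anchor, a right anchor and replacement sequence; the stretch
#' between the unique anchor occurrences is replaced. Assembly itself is
#' out of scope — this is the I/O hook for incorporating its output.
#'
#' @param consensus consensus sequence.
#' @param patches list of lists with `left`, `right` (anchor strings, each
#'   occurring exactly once) and `sequence` (replacement between anchors).
#' @return Patched sequence.
#' @export
splice_patches <- function(consensus, patches) {
  out <- consensus
  for (p in patches) {
    lpos <- gregexpr(p$left, out, fixed = TRUE)[[1]]
    rpos <- gregexpr(p$right, out, fixed = TRUE)[[1]]
    if (length(lpos) != 1 || lpos[1] == -1)
      stop("left anchor not found exactly once: ", p$left)
    if (length(rpos) != 1 || rpos[1] == -1)
      stop("right anchor not found exactly once: ", p$right)
    lend <- lpos[1] + nchar(p$left) - 1L
    if (rpos[1] <= lend) stop("anchors out of order or overlapping")
    out <- paste0(substr(out, 1, lend), p$sequence,
                  substr(out, rpos[1], nchar(out)))
  }
  out
}
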