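## Minimum-haplotype diversity from read-linked transversion variants:
## when two or more variable sites fall within one fragment length, the
## reads spanning them phase the alleles, and the number of distinct
## well-supported allele combinations is a lower bound on the number of
## haplotypes in the population.

#' Cluster variant positions into linkage windows
#'
#' Greedy left-to-right maximal chaining over sorted positions: a site
#' joins the current cluster while the cluster span (last - first + 1)
#' stays within `window_span`; clusters with at least two sites are
#' returned. Each site belongs to at most one cluster. Sites are pooled
#' across samples before windowing; scoring is per sample.
#'
#' @param positions sorted 0-based positions of transversion-only variant
#'   sites (pooled across samples).
#' @param window_span maximum window span in bp (default 35).
#' @return list of integer vectors (clusters of 0-based positions).
#' @export
find_linked_windows <- function(positions, window_span = 35L) {
  positions <- sort(unique(as.integer(positions)))
  clusters <- list()
  cur <- integer(0)
  for (p in positions) {
    if (!length(cur)) { cur <- p; next }
    if (p - cur[1] + 1L <= window_span) cur <- c(cur, p)
    else {
      if (length(cur) >= 2) clusters[[length(clusters) + 1L]] <- cur
      cur <- p
    }
  }
  if (length(cur) >= 2) clusters[[length(clusters) + 1L]] <- cur
  clusters
}

#' Phase one linkage window from spanning reads
#'
#' A read contributes iff its aligned span covers every cluster position;
#' its allele combination is the concatenation of its (reference-orientated)
#' bases at those positions. Combinations containing a base outside ACGT
#' are excluded.
#'
#' @param cluster integer vector of 0-based positions.
#' @param aln aligned-read data.frame.
#' @return Object of class `linked_window`: list with `positions`, `combos`
#'   (named integer vector: allele string -> spanning-read count),
#'   `n_spanning`, and (until [filter_and_count()]) empty `passing`/`count`.
#' @export
phase_window <- function(cluster, aln) {
  cluster <- sort(as.integer(cluster))
  lo <- cluster[1]; hi <- cluster[length(cluster)]
  ends <- aln$start + nchar(aln$seq)         # half-open end
  span <- aln$start <= lo & ends >= hi + 1L
  combos <- integer(0)
  if (any(span)) {
    sub <- aln[span, , drop = FALSE]
    mat <- vapply(cluster, function(p) {
      substr(sub$seq, p - sub$start + 1L, p - sub$start + 1L)
    }, character(nrow(sub)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
    keys <- toupper(apply(mat, 1, paste0, collapse = ""))
    valid <- !grepl("[^ACGT]", keys)
    tab <- table(keys[valid])
    combos <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(positions = cluster, combos = combos,
                 n_spanning = sum(combos), passing = character(0),
                 count = NA_integer_),
            class = "linked_window")
}

#' Remove low-frequency allele combinations and count survivors
#'
#' A combination passes iff it is supported by at least `min_reads`
#' spanning reads and by at least `min_fraction` of all spanning reads
#' (removal is strict: exactly 3 reads and exactly 15% is kept). The
#' passing count is the window's observed minimum number of haplotypes.
#'
#' @param win a [phase_window()] result.
#' @param min_reads minimum spanning reads per combination (default 3).
#' @param min_fraction minimum fraction of spanning reads (default 0.15).
#' @return The window with `passing` (surviving allele strings) and
#'   `count` filled in; `count` is 0 (flagged via `n_spanning`) for windows
#'   without spanning reads.
#' @export
filter_and_count <- function(win, min_reads = 3L, min_fraction = 0.15) {
  stopifnot(min_reads >= 1, min_fraction > 0, min_fraction < 1)
  if (win$n_spanning == 0) {
    win$passing <- character(0)
    win$count <- 0L
    return(win)
  }
  ok <- win$combos >= min_reads & win$combos / win$n_spanning >= min_fraction
  win$passing <- names(win$combos)[ok]
  win$count <- sum(ok)
  win
}

#' @export
print.linked_window <- function(x, ...) {
  cat(sprintf("linked window %s: %d spanning read(s), %d combination(s), %s passing\n",
              paste(x$positions, collapse = ","), x$n_spanning,
              length(x$combos),
              if (is.na(x$count)) "unfiltered" else as.character(x$count)))
  invisible(x)
}

#' Summarize phased windows into a minimum-haplotype estimate
#'
#' Per sample: the mean passing count over windows with spanning reads.
#' Overall: the minimum number of haplotypes demonstrably present, i.e.
#' the maximum passing count over all windows and samples — a window
#' showing k distinct well-supported phased combinations proves at least k
#' haplotypes. The estimate is a lower bound on the true diversity: the
#' support filters only remove combinations.
#'
#' @param windows_by_sample named list (sample -> list of filtered
#'   [filter_and_count()] windows).
#' @return Object of class `haplotype_summary`: list with `table`
#'   (data.frame: sample, positions, n_spanning, combos, count),
#'   `per_sample_mean`, `estimate`.
#' @export
summarize_haplotypes <- function(windows_by_sample) {
  rows <- list()
  for (s in names(windows_by_sample)) {
    for (w in windows_by_sample[[s]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s,
        positions = paste(w$positions + 1L, collapse = ","),
        n_spanning = w$n_spanning,
        combos = paste(sprintf("%s:%d", names(w$combos), w$combos), collapse = ";"),
        count = w$count, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no scorable linkage windows")
    return(structure(list(table = NULL, per_sample_mean = numeric(0),
                          estimate = NA_integer_),
                     class = "haplotype_summary"))
  }
  tab <- do.call(rbind, rows)
  scorable <- tab[tab$n_spanning > 0, , drop = FALSE]
  per_sample_mean <- tapply(scorable$count, scorable$sample, mean)
  estimate <- if (nrow(scorable)) max(scorable$count) else NA_integer_
  structure(list(table = tab,
                 per_sample_mean = per_sample_mean,
                 estimate = as.integer(estimate)),
            class = "haplotype_summary")
}

#' @export
print.haplotype_summary <- function(x, ...) {
  if (is.null(x$table)) { cat("haplotype summary: no scorable windows\n"); return(invisible(x)) }
  cat(sprintf("minimum haplotypes present: %d\n", x$estimate))
  for (s in names(x$per_sample_mean))
    cat(sprintf("  %s: mean per-window count %.2f\n", s, x$per_sample_mean[[s]]))
  invisible(x)
}

#' Full linkage analysis for one sample's alignment
#'
#' Convenience chain: window the pooled transversion-site positions, phase
#' each window from the sample's reads, apply the support filters.
#'
#' @param positions pooled 0-based transversion-site positions.
#' @param aln the sample's aligned-read data.frame.
#' @param cfg a [pipeline_config()].
#' @return list of filtered `linked_window`s.
#' @export
linkage_windows_for_sample <- function(positions, aln, cfg = pipeline_config()) {
  clusters <- find_linked_windows(positions, cfg$window_span)
  lapply(clusters, function(cl)
    filter_and_count(phase_window(cl, aln), cfg$hap_min_reads,
                     cfg$hap_min_fraction))
}
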