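## Taxonomic summarisation: naive-LCA assignment from tabular similarity
## hits, competitive reference-vs-database filtering, per-Mb normalisation,
## summary-table arithmetic and unique-mapping cross-tabulation.

#' Build a taxonomy tree from an edge list
#'
#' @param edges data.frame with columns `child`, `parent`, and optionally
#'   `rank`, `name`. The root is the node whose parent equals itself (or is
#'   NA).
#' @return Object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(edges) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  child <- as.character(edges$child); parent <- as.character(edges$parent)
  root <- child[is.na(parent) | parent == child]
  if (length(root) != 1) stop("taxonomy must have exactly one root")
  parent_map <- stats::setNames(parent, child)
  parent_map[root] <- NA_character_
  ## verify acyclic / rooted
  for (n in child) {
    seen <- character(0); cur <- n
    while (!is.na(parent_map[[cur]])) {
      if (cur %in% seen) stop("taxonomy contains a cycle at node ", n)
      seen <- c(seen, cur)
      cur <- parent_map[[cur]]
      if (!cur %in% child) stop("parent ", cur, " of ", seen[length(seen)],
                                " is not a node")
    }
  }
  structure(list(parent = parent_map, root = root,
                 rank = if ("rank" %in% names(edges))
                   stats::setNames(as.character(edges$rank), child) else NULL,
                 name = if ("name" %in% names(edges))
                   stats::setNames(as.character(edges$name), child) else NULL),
            class = "taxonomy_tree")
}

#' Read a taxonomy edge list from TSV
#'
#' Columns: child, parent, rank, name (tab-separated, header optional via
#' `header`).
#'
#' @param path TSV path.
#' @param header whether the file has a header row.
#' @return A [taxonomy_tree()].
#' @export
read_taxonomy <- function(path, header = TRUE) {
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("child", "parent", "rank", "name"))
  }
  taxonomy_tree(df)
}

ancestors_of <- function(tree, node) {
  out <- node
  while (!is.na(tree$parent[[node]])) {
    node <- tree$parent[[node]]
    out <- c(out, node)
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a [taxonomy_tree()].
#' @param taxa character vector of taxon ids.
#' @return The LCA taxon id.
#' @export
lca_of <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  bad <- setdiff(taxa, names(tree$parent))
  if (length(bad)) stop("unknown taxon id(s): ", paste(bad, collapse = ", "))
  paths <- lapply(taxa, function(t) rev(ancestors_of(tree, t)))
  k <- min(lengths(paths))
  lca <- tree$root
  for (i in seq_len(k)) {
    level <- unique(vapply(paths, `[[`, character(1), i))
    if (length(level) == 1) lca <- level else break
  }
  lca
}

#' Read tabular similarity hits (12+1 columns)
#'
#' Standard 12-column tabular hit format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore) plus a 13th taxon-id column. Query coverage percent
#' is derived as `100 * (qend - qstart + 1) / query length` when
#' `query_lengths` is supplied; otherwise it is set to 100 so the coverage
#' filter is inert (the tabular format does not carry query length).
#'
#' @param path TSV path (no header).
#' @param query_lengths optional named integer vector (query id -> length).
#' @return data.frame of hits with columns `query`, `subject`, `identity`,
#'   `length`, `evalue`, `bitscore`, `taxid`, `qcov`.
#' @export
read_hits <- function(path, query_lengths = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 13) stop("expected 13 tab-separated columns (12 + taxon id)")
  out <- data.frame(query = as.character(df[[1]]), subject = as.character(df[[2]]),
                    identity = as.numeric(df[[3]]), length = as.integer(df[[4]]),
                    qstart = as.integer(df[[7]]), qend = as.integer(df[[8]]),
                    evalue = as.numeric(df[[11]]), bitscore = as.numeric(df[[12]]),
                    taxid = as.character(df[[13]]), stringsAsFactors = FALSE)
  if (!is.null(query_lengths)) {
    ql <- query_lengths[out$query]
    out$qcov <- 100 * (abs(out$qend - out$qstart) + 1) / as.numeric(ql)
  } else out$qcov <- 100
  out
}

#' Naive lowest-common-ancestor taxonomic assignment
#'
#' Per query: hits failing the bitscore, e-value, identity or query-coverage
#' thresholds are dropped; of the survivors, only hits within `top_percent`
#' of the best bitscore are kept (inclusive boundary:
#' `bitscore >= (1 - p/100) * best`); the query is assigned the LCA of the
#' surviving hits' taxa. Taxa whose assigned-query tally falls below
#' `min_support` percent of all assigned queries are then reassigned to
#' their parent, repeatedly, until every assignment meets the support
#' threshold or reaches the root.
#'
#' @param hits a [read_hits()] data.frame.
#' @param tree a [taxonomy_tree()].
#' @param cfg a [pipeline_config()] (uses the `lca_*` keys).
#' @return Named character vector: query id -> assigned taxon id. Queries
#'   with no surviving hits are absent.
#' @export
naive_lca <- function(hits, tree, cfg = pipeline_config()) {
  keep <- hits$bitscore >= cfg$lca_min_score &
    hits$evalue <= cfg$lca_max_evalue &
    hits$identity >= cfg$lca_min_identity &
    hits$qcov >= cfg$lca_min_cover
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  assign_one <- function(h) {
    best <- max(h$bitscore)
    top <- h[h$bitscore >= (1 - cfg$lca_top_percent / 100) * best, , drop = FALSE]
    lca_of(tree, top$taxid)
  }
  assignments <- vapply(split(hits, hits$query), assign_one, character(1))
  ## min-support: move failing taxa up to their parents until supported
  n_assigned <- length(assignments)
  min_n <- cfg$lca_min_support / 100 * n_assigned
  repeat {
    tally <- table(assignments)
    failing <- names(tally)[tally < min_n & names(tally) != tree$root]
    if (!length(failing)) break
    for (tx in failing)
      assignments[assignments == tx] <- tree$parent[[tx]]
  }
  assignments
}

#' Competitive filter of reference-mapped reads against database hits
#'
#' A read mapped to a curated reference genome is retained iff its
#' reference bitscore beats its best database bitscore, or — when the
#' database matches as well or better — the LCA of the best-bitscore
#' database hits still lies within the target genus (the database merely
#' confirms the genus rather than contradicting the mapping).
#'
#' @param reads data.frame with `name`, `ref_bitscore`.
#' @param db_hits data.frame with `query`, `bitscore`, `taxid` (database
#'   hits; reads absent from it have no database match and are retained).
#' @param tree a [taxonomy_tree()].
#' @param target_genus taxon id of the reference genome's genus.
#' @return The retained subset of `reads`.
#' @export
competitive_filter <- function(reads, db_hits, tree, target_genus) {
  genus_set <- function(tx) target_genus %in% ancestors_of(tree, tx)
  keep <- vapply(seq_len(nrow(reads)), function(i) {
    h <- db_hits[db_hits$query == reads$name[i], , drop = FALSE]
    if (!nrow(h)) return(TRUE)
    best <- max(h$bitscore)
    if (reads$ref_bitscore[i] > best) return(TRUE)
    best_taxa <- unique(h$taxid[h$bitscore == best])
    lca <- lca_of(tree, best_taxa)
    lca == target_genus || genus_set(lca)
  }, logical(1))
  reads[keep, , drop = FALSE]
}

#' Mapped-read density per megabase of genome
#'
#' @param n_mapped retained mapped-read count.
#' @param genome_length genome length in bp.
#' @return Reads per Mb.
#' @export
reads_per_mb <- function(n_mapped, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  n_mapped / (genome_length / 1e6)
}

#' Metagenomic summary-table arithmetic
#'
#' For each taxon category: N identified sequences, I = 100 N / n_identified
#' and A = 100 N / n_analysed, both rounded to two decimals; rows sorted by
#' N descending.
#'
#' @param counts named numeric vector: taxon -> N.
#' @param n_identified total identified sequences.
#' @param n_analysed total sequences entering the analysis (passed
#'   explicitly, never inferred).
#' @return data.frame with `taxon`, `N`, `I`, `A`.
#' @export
summary_table <- function(counts, n_identified, n_analysed) {
  if (n_identified <= 0 || n_analysed <= 0) stop("zero denominator")
  if (n_identified > n_analysed) stop("n_identified exceeds n_analysed")
  if (any(counts > n_identified)) stop("category count exceeds n_identified")
  ord <- order(-counts)
  data.frame(taxon = names(counts)[ord], N = as.numeric(counts[ord]),
             I = round(100 * counts[ord] / n_identified, 2),
             A = round(100 * counts[ord] / n_analysed, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Unique and shared mapped reads across reference genomes
#'
#' @param id_sets named list: genome -> character vector of mapped read ids.
#' @return list with `unique` (named counts of reads mapping only to that
#'   genome) and `shared` (data.frame: genome_a, genome_b, n_shared for
#'   each unordered pair).
#' @export
unique_mapping_crosstab <- function(id_sets) {
  genomes <- names(id_sets)
  uniq <- vapply(genomes, function(g) {
    others <- unique(unlist(id_sets[setdiff(genomes, g)], use.names = FALSE))
    sum(!id_sets[[g]] %in% others)
  }, numeric(1))
  shared <- if (length(genomes) >= 2) {
    pairs <- utils::combn(genomes, 2)
    data.frame(genome_a = pairs[1, ], genome_b = pairs[2, ],
               n_shared = apply(pairs, 2, function(p)
                 length(intersect(id_sets[[p[1]]], id_sets[[p[2]]]))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(genome_a = character(0), genome_b = character(0),
               n_shared = integer(0), stringsAsFactors = FALSE)
  }
  list(unique = uniq, shared = shared)
}
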