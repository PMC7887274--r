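## Transversion-only variant analysis against the composite palaeogenome:
## calling, haplogroup (high/low-frequency) consensus splitting, replicated
## allele-proportion estimation, and damage-restricted validation.

#' Call polymorphic sites from a pileup
#'
#' A site is reported when at least two alleles each pass the noise floor
#' (count >= 2), the site depth reaches `min_cov`, and the site quality
#' reaches `min_qual`. Site quality is the Phred-scaled binomial tail
#' probability that the minor-allele count arose from base-calling error:
#' `-10 log10 P(X >= minor count)`, `X ~ Binomial(depth, e)` with `e` the
#' mean quality-implied error over the column's bases. Substitution-only —
#' indels are never considered.
#'
#' @param pileup a [build_pileup()] result (against the composite genome).
#' @param composite_ref composite reference the pileup was built against.
#' @param min_qual minimum site quality, Phred (default 30).
#' @param min_cov minimum depth (conventionally half the mean coverage).
#' @return Object of class `variant_sites`: data.frame with `pos` (0-based),
#'   `composite_base`, `depth`, `qual`, `is_transversion`, and list-columns
#'   `allele_base`, `allele_count`, `allele_prop` (comma-joined strings for
#'   portability).
#' @export
call_variants <- function(pileup, composite_ref, min_qual = 30, min_cov = 1L) {
  stopifnot(min_cov >= 1)
  refc <- seq_chars(toupper(composite_ref))
  cnt <- pileup$counts
  nalleles <- colSums(cnt >= 2L)
  cand <- which(nalleles >= 2L & pileup$depth >= min_cov)
  rows <- lapply(cand, function(p) {
    counts <- cnt[, p]
    keep <- counts >= 2L
    bases <- BASES[keep]
    counts <- counts[keep]
    ord <- order(-counts, bases)
    bases <- bases[ord]; counts <- counts[ord]
    depth <- pileup$depth[p]
    ebar <- phred_to_error(sum(pileup$qual_sum[, p]) / depth)
    minor <- counts[2]
    ptail <- stats::pbinom(minor - 1L, depth, ebar, lower.tail = FALSE)
    qual <- if (ptail <= 0) 1000 else min(1000, -10 * log10(ptail))
    props <- counts / sum(counts)
    tv <- all(outer(bases, bases, function(a, b)
      is_transversion_pair(a, b))[lower.tri(diag(length(bases)))])
    data.frame(pos = p - 1L, composite_base = refc[p], depth = depth,
               qual = qual, is_transversion = tv,
               allele_base = paste(bases, collapse = ","),
               allele_count = paste(counts, collapse = ","),
               allele_prop = paste(format(props, trim = TRUE, digits = 10),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), composite_base = character(0),
               depth = integer(0), qual = numeric(0),
               is_transversion = logical(0), allele_base = character(0),
               allele_count = character(0), allele_prop = character(0),
               stringsAsFactors = FALSE)
  out <- out[out$qual >= min_qual, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_sites", "data.frame")
  out
}

#' Drop rare alleles from called sites
#'
#' Removes alleles below the rare-allele proportion floor (strictly below:
#' exactly at the floor is kept) — rare alleles at well-covered sites are
#' dominated by residual deamination and sequencing noise. Proportions of
#' the surviving alleles are NOT renormalized (reported raw, with
#' `n_rare_dropped` flagging removals); `is_transversion` is re-evaluated
#' on the surviving alleles, and sites left monomorphic are dropped — this
#' is what lets genuine transversion sites survive a two-read damage
#' transition allele, the interplay that determines the haplogroup and
#' haplotype counts downstream.
#'
#' @param sites a [call_variants()] result.
#' @param floor proportion floor (default 0.1).
#' @return Filtered `variant_sites` with a `n_rare_dropped` column.
#' @export
apply_rare_allele_floor <- function(sites, floor = 0.1) {
  if (!nrow(sites)) {
    sites$n_rare_dropped <- integer(0)
    return(sites)
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    al <- site_alleles(sites, i)
    keep <- al$prop >= floor
    if (sum(keep) < 2) return(NULL)
    out <- sites[i, , drop = FALSE]
    out$allele_base <- paste(al$base[keep], collapse = ",")
    out$allele_count <- paste(al$count[keep], collapse = ",")
    out$allele_prop <- paste(format(al$prop[keep], trim = TRUE, digits = 10),
                             collapse = ",")
    b <- al$base[keep]
    out$is_transversion <- all(outer(b, b, is_transversion_pair)[lower.tri(diag(length(b)))])
    out$n_rare_dropped <- sum(!keep)
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    z <- sites[0, , drop = FALSE]; z$n_rare_dropped <- integer(0); z
  }
  rownames(out) <- NULL
  class(out) <- c("variant_sites", "data.frame")
  out
}

site_alleles <- function(sites, i) {
  list(base = strsplit(sites$allele_base[i], ",", fixed = TRUE)[[1]],
       count = as.integer(strsplit(sites$allele_count[i], ",", fixed = TRUE)[[1]]),
       prop = as.numeric(strsplit(sites$allele_prop[i], ",", fixed = TRUE)[[1]]))
}

#' Restrict to transversion-only sites
#'
#' Keeps sites at which every pair of observed alleles is a
#' purine/pyrimidine change; C/T and G/A pairs — the cytosine-deamination
#' artefact signature of ancient DNA — never qualify, so the retained set
#' is immune to damage-driven false positives. Idempotent.
#'
#' @param sites a [call_variants()] result.
#' @return Filtered `variant_sites`.
#' @export
transversions_only <- function(sites) {
  out <- sites[sites$is_transversion, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_sites", "data.frame")
  out
}

#' Split alleles into the high- and low-frequency haplogroup sets
#'
#' The high-frequency set at each site is the allele present in the
#' reconstructed composite genome — membership is by identity with the
#' composite base, not by frequency. All other alleles form the
#' low-frequency set. Sites whose alleles never include the composite base
#' are flagged and contribute all alleles to the low set.
#'
#' @param sites a [call_variants()] result.
#' @param composite_ref composite genome sequence.
#' @return list with `high` (data.frame pos/base), `low` (data.frame
#'   pos/base, possibly several rows per pos), `flagged` (positions whose
#'   alleles exclude the composite base).
#' @export
split_high_low <- function(sites, composite_ref) {
  refc <- seq_chars(toupper(composite_ref))
  high <- list(); low <- list(); flagged <- integer(0)
  for (i in seq_len(nrow(sites))) {
    al <- site_alleles(sites, i)
    cb <- refc[sites$pos[i] + 1L]
    if (cb %in% al$base) {
      high[[length(high) + 1L]] <- data.frame(pos = sites$pos[i], base = cb)
      others <- setdiff(al$base, cb)
      if (length(others))
        low[[length(low) + 1L]] <- data.frame(pos = sites$pos[i], base = others)
    } else {
      flagged <- c(flagged, sites$pos[i])
      low[[length(low) + 1L]] <- data.frame(pos = sites$pos[i], base = al$base)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(pos = integer(0), base = character(0))
  list(high = bind(high), low = bind(low), flagged = flagged)
}

#' Substitute chosen alleles into the composite genome
#'
#' @param composite_ref composite genome sequence.
#' @param chosen data.frame with `pos` (0-based, unique) and `base`; where
#'   several alleles share a position (multiallelic low set) the first is
#'   used.
#' @return Sequence with each site's chosen allele substituted; length
#'   preserved.
#' @export
apply_variant_consensus <- function(composite_ref, chosen) {
  out <- seq_chars(composite_ref)
  if (nrow(chosen)) {
    chosen <- chosen[!duplicated(chosen$pos), , drop = FALSE]
    if (any(chosen$pos < 0 | chosen$pos >= length(out)))
      stop("variant position out of bounds")
    out[chosen$pos + 1L] <- chosen$base
  }
  paste0(out, collapse = "")
}

#' Depth cutoff at a fraction of mean coverage
#'
#' "At least half the average coverage" pinned as: mean depth over all
#' reference positions (zeros included), times the fraction, floored; never
#' below 1.
#'
#' @param pileup a [build_pileup()] result.
#' @param fraction fraction of mean depth (default 0.5).
#' @return Integer depth cutoff.
#' @export
coverage_cutoff <- function(pileup, fraction = 0.5) {
  max(1L, as.integer(floor(pileup$mean_coverage * fraction)))
}

#' Replicated allele-proportion estimation against the haplogroup pair
#'
#' For each of `cfg$n_dedup_replicates` replicates: reads are mapped
#' separately against the high- and the low-frequency consensus (avoiding
#' reference bias), the two alignments merged, exact sequence duplicates
#' removed with the replicate's own random stream, coordinate duplicates
#' removed, variants re-called against the composite genome and restricted
#' to transversions, and alleles below `cfg$rare_allele_floor` dropped
#' (strictly below; exactly at the floor is kept — flagged, not
#' renormalized). Reported per site and replicate as the proportion of the
#' composite allele versus the alternative, plus the genome-wide mean
#' alternative proportion per replicate.
#'
#' @param reads read data.frame (`name`, `seq`, `qual`).
#' @param high_seq,low_seq the haplogroup consensus pair.
#' @param composite_ref composite genome sequence.
#' @param cfg a [pipeline_config()].
#' @param seed master seed; each replicate derives a labelled substream.
#' @param sample_id sample tag.
#' @return Object of class `proportion_report`: list with `per_site`
#'   (data.frame: replicate, pos, composite_base, alt_base, prop_composite,
#'   prop_alt, depth, n_rare_dropped), `per_replicate` (data.frame:
#'   replicate, mean_alt_proportion, n_sites), `n_replicates`.
#' @export
allele_proportions <- function(reads, high_seq, low_seq, composite_ref,
                               cfg = pipeline_config(), seed = 1L,
                               sample_id = "sample1") {
  stopifnot(cfg$n_dedup_replicates >= 1)
  per_site <- list(); per_rep <- list()
  for (r in seq_len(cfg$n_dedup_replicates)) {
    aln_h <- map_reads(reads, high_seq, cfg$max_mismatch_rate, sample_id)
    aln_l <- map_reads(reads, low_seq, cfg$max_mismatch_rate, sample_id)
    merged <- rbind(aln_h, aln_l)
    merged <- remove_exact_duplicates(merged, substream_seed(seed, "dedup_replicate", r))
    merged <- remove_coordinate_duplicates(merged)
    pk <- build_pileup(merged, composite_ref)
    sites <- call_variants(pk, composite_ref, cfg$var_min_qual,
                           coverage_cutoff(pk, cfg$var_cov_fraction))
    ## floor before the transversion restriction: a rare damage transition
    ## allele must not disqualify a genuine transversion site
    sites <- transversions_only(apply_rare_allele_floor(sites, cfg$rare_allele_floor))
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      al <- site_alleles(sites, i)
      cb <- sites$composite_base[i]
      p_comp <- if (cb %in% al$base) al$prop[al$base == cb] else 0
      alt <- setdiff(al$base, cb)
      p_alt <- if (length(alt)) sum(al$prop[al$base %in% alt]) else 0
      data.frame(replicate = r, pos = sites$pos[i], composite_base = cb,
                 alt_base = paste(alt, collapse = ","),
                 prop_composite = p_comp, prop_alt = p_alt,
                 depth = sites$depth[i],
                 n_rare_dropped = sites$n_rare_dropped[i],
                 stringsAsFactors = FALSE)
    })
    rows <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(rows)) {
      ## sites where only the composite allele survives are monomorphic
      ## after the floor; they do not enter the mean
      poly <- rows[nzchar(rows$alt_base), , drop = FALSE]
      per_site[[r]] <- rows
      per_rep[[r]] <- data.frame(replicate = r,
                                 mean_alt_proportion = if (nrow(poly)) mean(poly$prop_alt) else 0,
                                 n_sites = nrow(poly))
    } else {
      per_rep[[r]] <- data.frame(replicate = r, mean_alt_proportion = 0,
                                 n_sites = 0L)
    }
  }
  structure(list(per_site = if (length(per_site)) do.call(rbind, per_site) else
                   NULL,
                 per_replicate = do.call(rbind, per_rep),
                 n_replicates = cfg$n_dedup_replicates),
            class = "proportion_report")
}

#' @export
print.proportion_report <- function(x, ...) {
  cat(sprintf("allele proportions over %d replicate(s):\n", x$n_replicates))
  print(x$per_replicate, row.names = FALSE)
  invisible(x)
}

#' Fraction of variants recoverable from damaged reads alone
#'
#' Validates that called variants are not driven by modern contamination:
#' reads are restricted to those with PMD score at or above
#' `cfg$damage_score_threshold`, variants re-called on the damaged-only
#' pileup with the relaxed thresholds (`dmg_var_min_qual`,
#' `dmg_var_min_cov`) appropriate to the lower coverage, restricted to
#' transversions, and the fraction of original site positions recovered is
#' returned.
#'
#' @param sites transversion-only `variant_sites` from the full read set.
#' @param aln aligned-read data.frame (full set, against `reference`).
#' @param reference composite genome sequence.
#' @param cfg a [pipeline_config()].
#' @return Recall fraction in [0, 1]; attribute `n_damaged` gives the size
#'   of the damaged-only read set.
#' @export
damage_restricted_recall <- function(sites, aln, reference,
                                     cfg = pipeline_config()) {
  if (nrow(sites) == 0) stop("no original variant sites supplied")
  damaged <- filter_damaged(aln, reference, cfg$damage_score_threshold,
                            cfg$pmd_d, cfg$pmd_decay)
  if (nrow(damaged) == 0) {
    warning("no reads pass the damage score threshold; recall is 0")
    out <- 0
    attr(out, "n_damaged") <- 0L
    return(out)
  }
  pk <- build_pileup(damaged, reference)
  recalled <- transversions_only(apply_rare_allele_floor(
    call_variants(pk, reference, cfg$dmg_var_min_qual, cfg$dmg_var_min_cov),
    cfg$rare_allele_floor))
  out <- length(intersect(sites$pos, recalled$pos)) / nrow(sites)
  attr(out, "n_damaged") <- nrow(damaged)
  out
}

#' Write variant sites as a VCF-like tab-separated table
#'
#' 1-based positions, per the convention of emitted variant tables.
#'
#' @param sites a `variant_sites` data.frame.
#' @param path output path.
#' @export
write_variants <- function(sites, path) {
  write_tsv(data.frame(pos1 = sites$pos + 1L,
                       composite_base = sites$composite_base,
                       alleles = sites$allele_base,
                       counts = sites$allele_count,
                       proportions = sites$allele_prop,
                       qual = round(sites$qual, 2),
                       depth = sites$depth,
                       transversion = sites$is_transversion), path)
}
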