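## Synthetic ancient-DNA read simulator: known haplotype mixtures, short
## log-normal fragments, terminal cytosine deamination decaying inward,
## uniform sequencing error. Stands in for sediment shotgun libraries and
## carries full ground truth for every downstream stage.

#' Damage model for simulated ancient reads
#'
#' Position-z deamination probability is `d * decay^z`, z the 0-based
#' distance from the relevant read end: C->T from the 5' end, G->A from the
#' 3' end (double-stranded library behaviour, two-sided). Sequencing error
#' is uniform across positions and substitution targets.
#'
#' @param d5 probability of C->T at the 5'-terminal position.
#' @param d3 probability of G->A at the 3'-terminal position.
#' @param decay per-base geometric decay factor in (0, 1].
#' @param seq_error per-base uniform sequencing error probability.
#' @return An object of class `damage_model`.
#' @export
damage_model <- function(d5 = 0.3, d3 = 0.3, decay = 0.5, seq_error = 0.001) {
  stopifnot(d5 >= 0, d5 <= 1, d3 >= 0, d3 <= 1,
            decay > 0, decay <= 1, seq_error >= 0, seq_error <= 1)
  structure(list(d5 = d5, d3 = d3, decay = decay, seq_error = seq_error),
            class = "damage_model")
}

#' Fragment length model for simulated reads
#'
#' Lengths are drawn log-normal (location log(mean_length), scale `spread`)
#' and rejection-truncated to `[min_length, max_length]`, matching the 35 bp
#' minimum retained and 160 bp profile cap of degraded sedaDNA fragments.
#'
#' @param mean_length modal fragment length in bp.
#' @param spread sdlog of the log-normal.
#' @param min_length,max_length truncation bounds in bp.
#' @return An object of class `fragment_model`.
#' @export
fragment_model <- function(mean_length = 65, spread = 0.25,
                           min_length = 35L, max_length = 160L) {
  stopifnot(mean_length > 0, spread > 0, min_length >= 1,
            max_length >= min_length)
  structure(list(mean_length = mean_length, spread = spread,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "fragment_model")
}

## transversion partner(s) of a base; transition partner
tv_alternatives <- function(base) {
  switch(base, A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
}
ts_alternative <- function(base) {
  switch(base, A = "G", G = "A", C = "T", T = "C")
}

#' Construct a haplotype mixture with planted variant truth
#'
#' Builds a random reference and `n_haplotypes` equal-length haplotypes that
#' differ from it at planted variant sites. Each site carries the reference
#' base plus exactly one alternative base (a transversion or a transition by
#' site type), so observed alleles at transversion sites are always a
#' purine/pyrimidine pair. `linked_pairs` plants pairs of transversion sites
#' a fixed gap apart at which the haplotypes show pairwise-distinct two-base
#' combinations — the signal exploited by the read-linkage haplotype
#' estimator. Unlinked sites are spaced more than one linkage window apart.
#'
#' @param ref_length reference length in bp.
#' @param n_haplotypes number of haplotypes (1–4).
#' @param n_transversion_sites unlinked transversion-only sites to plant.
#' @param n_transition_sites unlinked transition sites to plant.
#' @param proportions mixture proportions, summing to 1.
#' @param linked_pairs integer vector of gaps (bp between the two positions
#'   of each planted linked transversion pair).
#' @param seed RNG seed.
#' @return An object of class `haplotype_set`: list with `reference`
#'   (string), `haplotypes` (character vector), `proportions`, and `truth`
#'   (data.frame: `pos` 0-based, `ref_base`, `alt_base`, per-haplotype base
#'   matrix `hap_bases`, `is_transversion`, `linked_pair` id or NA).
#' @export
make_haplotype_set <- function(ref_length, n_haplotypes = 2,
                               n_transversion_sites = 10,
                               n_transition_sites = 0,
                               proportions = rep(1 / n_haplotypes, n_haplotypes),
                               linked_pairs = integer(0), seed = 1L) {
  if (length(proportions) != n_haplotypes)
    stop("proportions must have one entry per haplotype")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  if (n_haplotypes > 4)
    stop("at most 4 haplotypes supported (binary sites give 4 linked combinations)")
  set.seed(substream_seed(seed, "make_haplotype_set"))
  reference <- random_dna(ref_length)
  refc <- seq_chars(reference)

  ## site layout: unlinked sites and pair anchors spaced > 35 + max gap apart
  ## keep sites a full read length from the ends: edge positions are
  ## covered by fewer fragments and would fail depth cutoffs spuriously
  margin <- 160L
  spacing <- 36L + max(c(0L, as.integer(linked_pairs)))
  n_anchor <- n_transversion_sites + n_transition_sites + length(linked_pairs)
  need <- 2L * margin + n_anchor * (spacing + 1L)
  if (ref_length < need)
    stop("ref_length too small to place ", n_anchor, " sites (need >= ", need, " bp)")
  anchors <- margin + (seq_len(n_anchor) - 1L) * spacing
  if (n_anchor > 1) anchors <- anchors[sample.int(n_anchor)]  # shuffle host anchors

  site_pos <- integer(0); site_type <- character(0); site_pair <- integer(0)
  i <- 1L
  for (g in as.integer(linked_pairs)) {
    pid <- length(unique(site_pair[!is.na(site_pair)])) + 1L
    site_pos <- c(site_pos, anchors[i], anchors[i] + g)
    site_type <- c(site_type, "tv", "tv")
    site_pair <- c(site_pair, pid, pid)
    i <- i + 1L
  }
  if (n_transversion_sites > 0) {
    site_pos <- c(site_pos, anchors[seq(i, i + n_transversion_sites - 1L)])
    site_type <- c(site_type, rep("tv", n_transversion_sites))
    site_pair <- c(site_pair, rep(NA_integer_, n_transversion_sites))
    i <- i + n_transversion_sites
  }
  if (n_transition_sites > 0) {
    site_pos <- c(site_pos, anchors[seq(i, i + n_transition_sites - 1L)])
    site_type <- c(site_type, rep("ts", n_transition_sites))
    site_pair <- c(site_pair, rep(NA_integer_, n_transition_sites))
  }
  ord <- order(site_pos)
  site_pos <- site_pos[ord]; site_type <- site_type[ord]; site_pair <- site_pair[ord]

  n_sites <- length(site_pos)
  hap_bases <- matrix("", n_sites, n_haplotypes)
  alt_base <- character(n_sites)
  for (s in seq_len(n_sites)) {
    rb <- refc[site_pos[s] + 1L]
    alt_base[s] <- if (site_type[s] == "tv") sample(tv_alternatives(rb), 1) else ts_alternative(rb)
  }
  ## allele assignment: haplotype 1 carries the reference allele everywhere
  ## (it is the reference lineage); others get ref/alt with >=1 alt per site.
  if (n_haplotypes == 1) {
    ## no variation: drop all sites
    site_pos <- integer(0); site_type <- character(0); site_pair <- integer(0)
    alt_base <- character(0); hap_bases <- matrix("", 0, 1)
    n_sites <- 0L
  } else {
    for (pid in unique(site_pair[!is.na(site_pair)])) {
      idx <- which(!is.na(site_pair) & site_pair == pid)  # two sites
      combos <- rbind(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
      ## haplotype 1 is the reference lineage (ref,ref); the others take
      ## distinct combos such that every pair position varies in >=1 haplotype
      repeat {
        others <- 1L + sample.int(3L, n_haplotypes - 1L)
        if (all(colSums(combos[others, , drop = FALSE]) >= 1)) break
      }
      pick <- combos[c(1L, others), , drop = FALSE]
      for (h in seq_len(n_haplotypes)) for (j in 1:2) {
        s <- idx[j]; rb <- refc[site_pos[s] + 1L]
        hap_bases[s, h] <- if (pick[h, j]) alt_base[s] else rb
      }
    }
    for (s in which(is.na(site_pair))) {
      rb <- refc[site_pos[s] + 1L]
      n_carry <- sample.int(n_haplotypes - 1L, 1)
      carriers <- 1L + sample.int(n_haplotypes - 1L, n_carry)
      hap_bases[s, ] <- rb
      hap_bases[s, carriers] <- alt_base[s]
    }
  }

  haplotypes <- character(n_haplotypes)
  for (h in seq_len(n_haplotypes)) {
    hc <- refc
    if (n_sites > 0) hc[site_pos + 1L] <- hap_bases[, h]
    haplotypes[h] <- paste0(hc, collapse = "")
  }
  truth <- data.frame(pos = site_pos,
                      ref_base = if (n_sites) refc[site_pos + 1L] else character(0),
                      alt_base = alt_base,
                      is_transversion = site_type == "tv",
                      linked_pair = site_pair,
                      stringsAsFactors = FALSE)
  if (n_sites) truth$hap_bases <- I(split(hap_bases, row(hap_bases)))
  structure(list(reference = reference, haplotypes = haplotypes,
                 proportions = proportions, truth = truth,
                 hap_base_matrix = hap_bases),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes over %d bp, %d truth sites (%d transversion-only)\n",
              length(x$haplotypes), nchar(x$reference), nrow(x$truth),
              sum(x$truth$is_transversion)))
  invisible(x)
}

apply_damage_and_error <- function(read, dmg) {
  ch <- seq_chars(read)
  n <- length(ch)
  z5 <- 0:(n - 1)
  z3 <- (n - 1):0
  if (dmg$d5 > 0) {
    p <- dmg$d5 * dmg$decay^z5
    hit <- ch == "C" & stats::runif(n) < p
    ch[hit] <- "T"
  }
  if (dmg$d3 > 0) {
    p <- dmg$d3 * dmg$decay^z3
    hit <- ch == "G" & stats::runif(n) < p
    ch[hit] <- "A"
  }
  if (dmg$seq_error > 0) {
    hit <- which(stats::runif(n) < dmg$seq_error)
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  }
  paste0(ch, collapse = "")
}

#' Simulate ancient-DNA-like reads from a haplotype mixture
#'
#' Each fragment is drawn from a haplotype with its mixture probability,
#' placed uniformly, truncated-log-normal in length, deaminated at its
#' read-relative termini (C->T from 5', G->A from 3') before uniform
#' sequencing error, and emitted with per-base qualities consistent with
#' the error rate. Half the reads (Bernoulli 0.5) are reverse-complemented
#' in the FASTQ to exercise strand handling; damage is applied in read
#' coordinates before reverse-complementing, matching the biological
#' mechanism. The truth table stores reference-orientation sequences and
#' error-free coordinates.
#'
#' @param hs a [make_haplotype_set()] result.
#' @param coverage target fold coverage (expected total bases ≈ coverage ×
#'   reference length).
#' @param frag a [fragment_model()].
#' @param dmg a [damage_model()].
#' @param seed RNG seed.
#' @param sample_id sample tag carried into the truth table.
#' @return list with `reads` (data.frame name/seq/qual as sequenced) and
#'   `truth` (data.frame: name, hap, start 0-based, length, strand,
#'   ref_orient_seq).
#' @export
simulate_reads <- function(hs, coverage, frag = fragment_model(),
                           dmg = damage_model(), seed = 1L,
                           sample_id = "sample1") {
  stopifnot(inherits(hs, "haplotype_set"), coverage > 0)
  set.seed(substream_seed(seed, "simulate_reads"))
  L <- nchar(hs$reference)
  target <- coverage * L
  mean_len <- min(max(frag$mean_length, frag$min_length), frag$max_length)
  n_guess <- ceiling(target / mean_len * 1.3) + 10L

  draw_lengths <- function(n) {
    out <- integer(0)
    while (length(out) < n) {
      x <- round(stats::rlnorm(n, meanlog = log(frag$mean_length), sdlog = frag$spread))
      x <- x[x >= frag$min_length & x <= frag$max_length & x <= L]
      out <- c(out, x)
    }
    out[seq_len(n)]
  }
  lens <- draw_lengths(n_guess)
  keep_n <- which(cumsum(lens) >= target)[1]
  if (is.na(keep_n)) keep_n <- n_guess
  lens <- lens[seq_len(keep_n)]
  n <- length(lens)

  hap_idx <- sample.int(length(hs$haplotypes), n, replace = TRUE, prob = hs$proportions)
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1) - 1L, integer(1))
  minus <- stats::runif(n) < 0.5
  err_q <- if (dmg$seq_error > 0) {
    min(40L, max(2L, as.integer(round(-10 * log10(dmg$seq_error)))))
  } else 40L

  seqs <- character(n); quals <- character(n); names_ <- character(n)
  ref_orient <- character(n)
  for (i in seq_len(n)) {
    frag_seq <- substr(hs$haplotypes[hap_idx[i]], starts[i] + 1L, starts[i] + lens[i])
    read <- if (minus[i]) revcomp(frag_seq) else frag_seq
    read <- apply_damage_and_error(read, dmg)
    seqs[i] <- read
    ref_orient[i] <- if (minus[i]) revcomp(read) else read
    quals[i] <- strrep(intToUtf8(err_q + 33L), lens[i])
    names_[i] <- sprintf("%s_read%06d", sample_id, i)
  }
  reads <- data.frame(name = names_, seq = seqs, qual = quals,
                      stringsAsFactors = FALSE)
  truth <- data.frame(name = names_, hap = hap_idx, start = starts,
                      length = lens, strand = ifelse(minus, "-", "+"),
                      ref_orient_seq = ref_orient, sample_id = sample_id,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Convert simulation truth records to aligned reads
#'
#' Error-free coordinates from the generator, in the internal aligned-read
#' representation (reference orientation), bypassing the mapper.
#'
#' @param sim a [simulate_reads()] result.
#' @param reference reference sequence the coordinates refer to.
#' @return An aligned-read data.frame (see [map_reads()]).
#' @export
truth_alignments <- function(sim, reference) {
  t <- sim$truth
  qual <- sim$reads$qual[match(t$name, sim$reads$name)]
  qual <- ifelse(t$strand == "-",
                 vapply(qual, function(q) paste(rev(seq_chars(q)), collapse = ""),
                        character(1), USE.NAMES = FALSE),
                 qual)
  data.frame(name = t$name, seq = t$ref_orient_seq, qual = qual,
             start = t$start, strand = t$strand, sample_id = t$sample_id,
             nm = NA_integer_, stringsAsFactors = FALSE)
}

#' Write simulation truth as a minimal SAM file
#'
#' @param sim a [simulate_reads()] result.
#' @param reference reference sequence.
#' @param ref_name reference name for the SAM header.
#' @param path output path.
#' @export
write_truth_sam <- function(sim, reference, ref_name = "ref", path) {
  write_sam(truth_alignments(sim, reference), reference, ref_name, path)
}
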