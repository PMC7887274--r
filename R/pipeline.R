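## End-to-end driver: filter -> map -> dedup -> consensus -> damage ->
## variants -> proportions -> haplotypes, with all stage outputs written to
## an output directory and a machine-readable summary. Identical seed and
## inputs give byte-identical outputs.

#' Run the full sedaDNA organellar pipeline
#'
#' Executes the complete chain on one or more read sets against a seed
#' reference: read filtering (length + DUST), iterative composite-genome
#' reconstruction, deamination profiling, transversion-only variant
#' calling, high/low-frequency haplogroup consensus splitting, replicated
#' allele-proportion estimation, damage-restricted validation, and the
#' read-linkage minimum-haplotype estimate (sites pooled across samples,
#' scored per sample). Stage outputs are written under `out_dir`; the
#' summary is tab-separated key-value pairs.
#'
#' @param reads_paths named character vector of FASTQ paths (names are
#'   sample ids; a single unnamed path becomes sample1).
#' @param seed_reference_path FASTA path of the seed genome.
#' @param out_dir output directory (created if needed).
#' @param cfg a [pipeline_config()].
#' @param seed master seed; stages derive labelled substreams.
#' @return Invisibly, a list with the summary and the main stage objects.
#' @export
run_pipeline <- function(reads_paths, seed_reference_path, out_dir,
                         cfg = pipeline_config(), seed = cfg$rng_seed) {
  if (is.null(names(reads_paths)) || any(!nzchar(names(reads_paths))))
    names(reads_paths) <- paste0("sample", seq_along(reads_paths))
  for (p in reads_paths) if (!file.exists(p)) stop("reads file not found: ", p)
  if (!file.exists(seed_reference_path))
    stop("seed reference not found: ", seed_reference_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed_ref <- read_fasta(seed_reference_path)[[1]]
  summary_kv <- list(seed = seed)
  stage <- function(name, expr) {
    log_stage(name, "...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  ## 1. filter
  samples <- list()
  for (s in names(reads_paths)) {
    fr <- stage(paste0("filter:", s), {
      filter_reads(read_fastq(reads_paths[[s]]), cfg)
    })
    if (nrow(fr$reads) == 0)
      stop("pipeline stage 'filter:", s, "' failed: empty read set after filtering")
    samples[[s]] <- fr$reads
    summary_kv[[paste0(s, ".n_input")]] <- fr$report$n_input
    summary_kv[[paste0(s, ".n_retained")]] <- fr$report$n_retained
  }
  pooled <- do.call(rbind, samples)

  ## 2. composite consensus from pooled reads
  cons <- stage("consensus", iterate_consensus(pooled, seed_ref, cfg))
  composite <- cons$sequence
  write_fasta(c(composite = composite), file.path(out_dir, "composite.fasta"))
  write_tsv(data.frame(iteration = seq_along(cons$edits), edits = cons$edits),
            file.path(out_dir, "consensus_iterations.tsv"))
  write_tsv(cons$gaps, file.path(out_dir, "coverage_gaps.bed"))
  summary_kv$consensus_iterations <- cons$n_iterations
  summary_kv$consensus_converged <- cons$converged
  summary_kv$mean_coverage <- sprintf("%.4f", cons$mean_coverage)

  ## 3. per-sample mapping to the composite + dedup
  aln <- list()
  for (s in names(samples)) {
    a <- stage(paste0("map:", s), {
      a <- map_reads(samples[[s]], composite, cfg$max_mismatch_rate, s)
      remove_coordinate_duplicates(
        remove_exact_duplicates(a, substream_seed(seed, paste0("map_dedup_", s))))
    })
    aln[[s]] <- a
    write_sam(a, composite, "composite", file.path(out_dir, paste0(s, ".sam")))
    summary_kv[[paste0(s, ".n_mapped")]] <- nrow(a)
  }

  ## 4. damage profiles
  for (s in names(aln)) {
    prof <- stage(paste0("damage:", s),
                  damage_profile(aln[[s]], composite,
                                 length_cap = cfg$profile_length_cap))
    write_damage_profile(prof, file.path(out_dir, paste0(s, ".damage.tsv")))
    summary_kv[[paste0(s, ".ct5_0")]] <- sprintf("%.4f", prof$ct5[1])
  }

  ## 5. variants per sample against the composite
  sites_by_sample <- list()
  for (s in names(aln)) {
    sites <- stage(paste0("variants:", s), {
      pk <- build_pileup(aln[[s]], composite)
      transversions_only(apply_rare_allele_floor(
        call_variants(pk, composite, cfg$var_min_qual,
                      coverage_cutoff(pk, cfg$var_cov_fraction)),
        cfg$rare_allele_floor))
    })
    sites_by_sample[[s]] <- sites
    write_variants(sites, file.path(out_dir, paste0(s, ".variants.tsv")))
    summary_kv[[paste0(s, ".n_tv_variants")]] <- nrow(sites)
  }

  ## 6. haplogroup consensus pair (pooled sites), proportions, damage recall
  pooled_aln <- do.call(rbind, aln)
  pooled_pk <- build_pileup(pooled_aln, composite)
  pooled_sites <- transversions_only(apply_rare_allele_floor(
    call_variants(pooled_pk, composite, cfg$var_min_qual,
                  coverage_cutoff(pooled_pk, cfg$var_cov_fraction)),
    cfg$rare_allele_floor))
  hl <- split_high_low(pooled_sites, composite)
  high_seq <- apply_variant_consensus(composite, hl$high)
  low_seq <- apply_variant_consensus(composite, hl$low)
  write_fasta(c(high = high_seq, low = low_seq),
              file.path(out_dir, "haplogroups.fasta"))
  summary_kv$n_pooled_tv_variants <- nrow(pooled_sites)
  summary_kv$n_haplogroups <- if (nrow(hl$low) > 0) 2L else 1L

  for (s in names(samples)) {
    prop <- stage(paste0("proportions:", s),
                  allele_proportions(samples[[s]], high_seq, low_seq, composite,
                                     cfg, substream_seed(seed, paste0("prop_", s)), s))
    write_tsv(prop$per_replicate, file.path(out_dir, paste0(s, ".proportions.tsv")))
    if (!is.null(prop$per_site))
      write_tsv(prop$per_site, file.path(out_dir, paste0(s, ".proportions_sites.tsv")))
    summary_kv[[paste0(s, ".mean_alt_proportion")]] <-
      sprintf("%.4f", mean(prop$per_replicate$mean_alt_proportion))
  }

  for (s in names(aln)) {
    if (nrow(sites_by_sample[[s]]) == 0) next
    rec <- stage(paste0("damage_recall:", s),
                 suppressWarnings(damage_restricted_recall(
                   sites_by_sample[[s]], aln[[s]], composite, cfg)))
    summary_kv[[paste0(s, ".damage_recall")]] <- sprintf("%.4f", as.numeric(rec))
  }

  ## 7. read-linkage minimum-haplotype estimate
  windows <- stage("haplotypes", {
    lapply(aln, function(a)
      linkage_windows_for_sample(pooled_sites$pos, a, cfg))
  })
  hap <- summarize_haplotypes(windows)
  if (!is.null(hap$table))
    write_tsv(hap$table, file.path(out_dir, "linked_windows.tsv"))
  summary_kv$min_haplotypes <- hap$estimate
  for (s in names(hap$per_sample_mean))
    summary_kv[[paste0(s, ".mean_window_count")]] <-
      sprintf("%.4f", hap$per_sample_mean[[s]])

  write_kv(summary_kv, file.path(out_dir, "summary.tsv"))
  log_stage("done", "summary written to ", file.path(out_dir, "summary.tsv"))
  invisible(list(summary = summary_kv, consensus = cons,
                 sites = sites_by_sample, pooled_sites = pooled_sites,
                 haplogroups = list(high = high_seq, low = low_seq),
                 haplotypes = hap))
}
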