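test_that("variant calling reports real polymorphism and scores minors by the binomial tail", {
  ref <- strrep("C", 10)
  ## monomorphic column: no site
  pk <- pileup_from_counts(list(`4` = c(C = 50)), ref)
  expect_equal(nrow(call_variants(pk, ref, 30, 1)), 0L)

  ## clean biallelic site: proportions and transversion flag
  refA <- paste0("A", strrep("C", 9))
  pk2 <- pileup_from_counts(list(`0` = c(A = 30, T = 20)), refA)
  sites <- call_variants(pk2, refA, 30, 1)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 0L)
  expect_true(sites$is_transversion)
  expect_equal(sites$allele_base, "A,T")
  expect_equal(as.numeric(strsplit(sites$allele_prop, ",")[[1]]), c(0.6, 0.4))

  ## minor-allele quality equals the exact binomial-tail oracle
  ## C:48, T:2 at Phred 40 -> e = 1e-4
  pk3 <- pileup_from_counts(list(`4` = c(C = 48, T = 2)), ref, qual = 40)
  s3 <- call_variants(pk3, ref, 0, 1)
  expect_equal(nrow(s3), 1L)
  q_oracle <- -10 * log10(oracle_binom_tail(2, 50, 1e-4))
  expect_equal(s3$qual, q_oracle, tolerance = 1e-8)
  ## inclusion decided by min_qual on exactly that statistic
  expect_equal(nrow(call_variants(pk3, ref, q_oracle + 1, 1)), 0L)
  expect_equal(nrow(call_variants(pk3, ref, q_oracle - 1, 1)), 1L)

  ## depth below min_cov excludes
  expect_equal(nrow(call_variants(pk2, refA, 30, 51)), 0L)
  ## single-read alleles never count (noise floor = 2)
  pk4 <- pileup_from_counts(list(`4` = c(C = 49, T = 1)), ref)
  expect_equal(nrow(call_variants(pk4, ref, 0, 1)), 0L)
})

test_that("transversion restriction drops deamination-confusable and mixed sites", {
  ref <- strrep("A", 6)
  pk <- pileup_from_counts(list(`0` = c(C = 30, T = 20),    # transition pair
                                `2` = c(A = 30, C = 20),    # transversion
                                `4` = c(A = 20, C = 20, T = 10)), # mixed: A/T ok, A/C ok, C/T not
                           ref)
  sites <- call_variants(pk, ref, 0, 1)
  expect_equal(nrow(sites), 3L)
  tv <- transversions_only(sites)
  expect_equal(tv$pos, 2L)
  expect_identical(transversions_only(tv), tv)   # idempotent
})

test_that("rare-allele floor removes noise alleles and re-evaluates transversion status", {
  ref <- strrep("G", 8)
  ## true transversion G/T plus a 2-read damage transition A
  pk <- pileup_from_counts(list(`3` = c(G = 60, T = 40, A = 2)), ref)
  sites <- call_variants(pk, ref, 30, 1)
  expect_false(sites$is_transversion)            # raw call is multiallelic with G/A
  floored <- apply_rare_allele_floor(sites, 0.1)
  expect_equal(nrow(floored), 1L)
  expect_true(floored$is_transversion)           # damage allele gone
  expect_equal(floored$allele_base, "G,T")
  expect_equal(floored$n_rare_dropped, 1L)
  ## proportions stay raw (not renormalized)
  expect_equal(as.numeric(strsplit(floored$allele_prop, ",")[[1]]),
               c(60, 40) / 102)

  ## a site whose alternative sits below the floor drops out entirely
  pk2 <- pileup_from_counts(list(`3` = c(G = 91, T = 9)), ref)
  s2 <- call_variants(pk2, ref, 0, 1)
  expect_equal(nrow(s2), 1L)
  expect_equal(nrow(apply_rare_allele_floor(s2, 0.1)), 0L)
  ## exactly at the floor is kept (strict "<" removal)
  pk3 <- pileup_from_counts(list(`3` = c(G = 90, T = 10)), ref)
  s3 <- apply_rare_allele_floor(call_variants(pk3, ref, 0, 1), 0.1)
  expect_equal(nrow(s3), 1L)
})

test_that("high/low split is by composite-genome membership, not frequency", {
  ref <- "ACGTACGTAC"
  sites <- call_variants(
    pileup_from_counts(list(`0` = c(A = 60, T = 40),   # composite allele major
                            `4` = c(T = 60, A = 40)),  # composite allele minor (seed A)
                       ref), ref, 0, 1)
  hl <- split_high_low(sites, ref)
  expect_equal(hl$high$pos, c(0L, 4L))
  expect_equal(hl$high$base, c("A", "A"))        # frequency does NOT decide
  expect_equal(hl$low$pos, c(0L, 4L))
  expect_equal(hl$low$base, c("T", "T"))
  expect_length(hl$flagged, 0L)

  ## degenerate: composite base absent -> flagged, all alleles to low
  s2 <- call_variants(pileup_from_counts(list(`0` = c(C = 30, G = 20)), ref),
                      ref, 0, 1)
  hl2 <- split_high_low(s2, ref)
  expect_equal(hl2$flagged, 0L)
  expect_equal(nrow(hl2$high), 0L)
  expect_setequal(hl2$low$base, c("C", "G"))
})

test_that("variant-consensus substitution changes exactly the chosen sites", {
  set.seed(61)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  expect_identical(apply_variant_consensus(ref, data.frame(pos = integer(0),
                                                           base = character(0))),
                   ref)
  pos <- sort(sample(0:499, 10))
  refc <- strsplit(ref, "")[[1]]
  base <- vapply(pos, function(p)
    setdiff(c("A", "C", "G", "T"), refc[p + 1])[1], character(1))
  out <- apply_variant_consensus(ref, data.frame(pos = pos, base = base))
  oc <- strsplit(out, "")[[1]]
  expect_equal(which(oc != refc) - 1L, pos)
  expect_error(apply_variant_consensus(ref, data.frame(pos = 500L, base = "A")),
               "bounds")
})

test_that("the haplogroup consensus pair recovers both true haplotypes from a mixture", {
  hs <- make_haplotype_set(3000, 2, n_transversion_sites = 8,
                           proportions = c(0.6, 0.4), linked_pairs = 20, seed = 62)
  sim <- simulate_reads(hs, coverage = 60,
                        dmg = damage_model(0.3, 0.3, 0.5, 0.001), seed = 62)
  aln <- remove_coordinate_duplicates(
    remove_exact_duplicates(map_reads(sim$reads, hs$reference), 62))
  pk <- build_pileup(aln, hs$reference)
  sites <- transversions_only(apply_rare_allele_floor(
    call_variants(pk, hs$reference, 30, coverage_cutoff(pk)), 0.1))
  expect_gte(nrow(sites), 0.9 * nrow(hs$truth))
  ## all called positions are planted positions
  expect_true(all(sites$pos %in% hs$truth$pos))
  hl <- split_high_low(sites, hs$reference)
  high <- apply_variant_consensus(hs$reference, hl$high)
  low <- apply_variant_consensus(hs$reference, hl$low)
  ## at every called truth site the pair shows the two true alleles
  for (i in which(hs$truth$pos %in% sites$pos)) {
    p <- hs$truth$pos[i] + 1
    expect_equal(substr(high, p, p), hs$hap_base_matrix[i, 1])
    expect_equal(substr(low, p, p), hs$hap_base_matrix[i, 2])
  }
})

test_that("replicated allele proportions recover the mixture and drop rare alleles", {
  cfg <- pipeline_config(n_dedup_replicates = 3L)
  ## single haplotype: alternative proportion identically 0
  h1 <- make_haplotype_set(1500, 1, 0, 0, proportions = 1, seed = 63)
  s1 <- simulate_reads(h1, coverage = 50, dmg = damage_model(0.3, 0.3, 0.5, 0.001),
                       seed = 63)
  pr1 <- allele_proportions(s1$reads, h1$reference, h1$reference, h1$reference,
                            cfg, seed = 63)
  expect_equal(pr1$per_replicate$mean_alt_proportion, rep(0, 3))

  ## 0.95/0.05 mixture: the 5% allele sits under the 0.1 floor and is dropped
  h2 <- make_haplotype_set(1500, 2, 4, proportions = c(0.95, 0.05), seed = 64)
  s2 <- simulate_reads(h2, coverage = 100, dmg = damage_model(0, 0, 0.5, 0),
                       seed = 64)
  hl2 <- list(high = data.frame(pos = h2$truth$pos,
                                base = h2$hap_base_matrix[, 1]),
              low = data.frame(pos = h2$truth$pos,
                               base = h2$hap_base_matrix[, 2]))
  high2 <- apply_variant_consensus(h2$reference, hl2$high)
  low2 <- apply_variant_consensus(h2$reference, hl2$low)
  pr2 <- allele_proportions(s2$reads, high2, low2, h2$reference, cfg, seed = 64)
  expect_equal(pr2$per_replicate$mean_alt_proportion, rep(0, 3))
})

test_that("damage-restricted validation recovers variants from damaged reads only", {
  cfg <- pipeline_config()
  hs <- make_haplotype_set(3000, 2, 8, proportions = c(0.6, 0.4), seed = 65)
  sim <- simulate_reads(hs, coverage = 100,
                        dmg = damage_model(0.3, 0.3, 0.5, 0.001), seed = 65)
  aln <- remove_coordinate_duplicates(
    remove_exact_duplicates(map_reads(sim$reads, hs$reference), 65))
  pk <- build_pileup(aln, hs$reference)
  sites <- transversions_only(apply_rare_allele_floor(
    call_variants(pk, hs$reference, 30, coverage_cutoff(pk)), 0.1))
  expect_gte(nrow(sites), 6L)
  rec <- damage_restricted_recall(sites, aln, hs$reference, cfg)
  expect_gte(as.numeric(rec), 0.5)
  expect_gt(attr(rec, "n_damaged"), 0L)

  ## damage-free data: nothing passes the PMD threshold, recall 0 with warning
  sim0 <- simulate_reads(hs, coverage = 40, dmg = damage_model(0, 0, 0.5, 0),
                         seed = 66)
  aln0 <- map_reads(sim0$reads, hs$reference)
  expect_warning(r0 <- damage_restricted_recall(sites, aln0, hs$reference, cfg),
                 "recall is 0")
  expect_equal(as.numeric(r0), 0)

  ## weakening the threshold never lowers recall
  cfg_weak <- pipeline_config(damage_score_threshold = 1e-9)
  rec_weak <- damage_restricted_recall(sites, aln, hs$reference, cfg_weak)
  expect_gte(as.numeric(rec_weak), as.numeric(rec))
})
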