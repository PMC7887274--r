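test_that("mapper places exact and reverse-complement substrings correctly", {
  set.seed(21)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  frag <- substr(ref, 101, 140)
  reads <- make_reads(c(frag, oracle_revcomp(frag)))
  aln <- map_reads(reads, ref)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$start, c(100L, 100L))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$nm, c(0L, 0L))
  ## stored sequences are reference-orientated
  expect_equal(aln$seq, c(frag, frag))
})

test_that("mapper placements equal the exhaustive Hamming-scan oracle", {
  set.seed(22)
  for (i in 1:15) {
    ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    pos <- sample(0:(300 - 40), 1)
    frag <- substr(ref, pos + 1, pos + 40)
    fc <- strsplit(frag, "")[[1]]
    mut <- sample(20, 2)   # leave an intact 16-mer for the seeding contract
    for (m in mut) fc[m] <- sample(setdiff(c("A", "C", "G", "T"), fc[m]), 1)
    read <- paste0(fc, collapse = "")
    if (sample(c(TRUE, FALSE), 1)) read <- oracle_revcomp(read)
    aln <- map_reads(make_reads(read), ref)
    o <- oracle_map(ref, read)
    expect_equal(nrow(aln), 1L)
    expect_equal(aln$start, o$pos)
    expect_equal(aln$strand, o$strand)
    expect_equal(aln$nm, o$mm)
  }
})

test_that("reads beyond the mismatch-rate cap are dropped, not misplaced", {
  set.seed(23)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  junk <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  aln <- map_reads(make_reads(junk), ref, max_mismatch_rate = 0.1)
  expect_equal(nrow(aln), 0L)
  expect_equal(attr(aln, "n_unmapped"), 1L)
})

test_that("exact-duplicate removal keeps one uniformly random copy", {
  a <- aligned(rep("ACGTACGTACGTACGTACGTACGTACGTACGTACGT", 2), c(10L, 55L))
  a <- rbind(a, aligned("ACGTACGTACGTACGTACGTACGTACGTACGTACGT", 10L, name = "a3"))
  out <- remove_exact_duplicates(a, 7)
  expect_equal(nrow(out), 1L)

  distinct <- aligned(c("AAACCCGGGTTTAAACCCGGGTTTAAACCCGGGTTT",
                        "CCCAAAGGGTTTCCCAAAGGGTTTCCCAAAGGGTTT"), c(0L, 40L))
  expect_identical(remove_exact_duplicates(distinct, 1), distinct)

  ## a minus-strand copy of the same molecule is still a duplicate
  fwd <- "ACGGATCCTAGCATGCAGTACCGGATCCTAGCATGG"
  pair <- aligned(c(fwd, fwd), c(5L, 80L), strand = c("+", "-"))
  expect_equal(nrow(remove_exact_duplicates(pair, 3)), 2L)  # different as-sequenced strings

  ## uniformity over replicate seeds
  dup <- aligned(rep("ACGTACGTACGTACGTACGTACGTACGTACGTACGT", 2), c(10L, 55L),
                 name = c("first", "second"))
  kept <- vapply(1:1000, function(s)
    remove_exact_duplicates(dup, s)$name, character(1))
  p <- mean(kept == "first")
  expect_gt(p, 0.45)
  expect_lt(p, 0.55)
})

test_that("coordinate-duplicate removal keeps the highest-quality copy per (start,strand,length)", {
  q30 <- strrep("?", 40)   # Phred 30
  q35 <- strrep("D", 40)   # Phred 35
  s <- strrep("ACGT", 10)
  a <- aligned(c(s, s), c(10L, 10L), qual = c(q30, q35), name = c("lo", "hi"))
  expect_equal(remove_coordinate_duplicates(a)$name, "hi")

  ## same start, opposite strand: both retained
  b <- aligned(c(s, s), c(10L, 10L), strand = c("+", "-"))
  expect_equal(nrow(remove_coordinate_duplicates(b)), 2L)

  ## randomized clusters: survivor count equals distinct key count; idempotent
  set.seed(31)
  starts <- sample(0:50, 120, replace = TRUE)
  lens <- sample(c(36, 40), 120, replace = TRUE)
  strands <- sample(c("+", "-"), 120, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  r <- aligned(seqs, as.integer(starts), strand = strands)
  out <- remove_coordinate_duplicates(r)
  expect_equal(nrow(out), length(unique(paste(starts, strands, lens))))
  expect_identical(remove_coordinate_duplicates(out), out)
})

test_that("pileup depth equals the naive interval-stabbing oracle", {
  set.seed(33)
  L <- 200
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  ## one perfect read
  one <- aligned(substr(ref, 101, 140), 100L)
  pk1 <- build_pileup(one, ref)
  expect_equal(pk1$depth[101:140], rep(1L, 40))
  expect_equal(sum(pk1$depth), 40L)
  for (p in 101:140)
    expect_equal(unname(pk1$counts[substr(ref, p, p), p]), 1L)

  ## no reads
  pk0 <- build_pileup(aligned(character(0), integer(0)), ref)
  expect_true(all(pk0$depth == 0L))

  ## random read set vs oracle
  n <- 60
  lens <- sample(35:60, n, replace = TRUE)
  starts <- vapply(lens, function(l) sample(0:(L - l), 1), numeric(1))
  seqs <- vapply(seq_len(n), function(i)
    substr(ref, starts[i] + 1, starts[i] + lens[i]), character(1))
  aln <- aligned(seqs, as.integer(starts))
  pk <- build_pileup(aln, ref)
  expect_equal(pk$depth, oracle_stab(starts, lens, L))
  expect_equal(pk$mean_coverage, sum(lens) / L)
  ## perfect reads: zero non-reference counts
  refc <- strsplit(ref, "")[[1]]
  for (p in seq_len(L)) expect_equal(pk$depth[p], unname(pk$counts[refc[p], p]))

  ## overrun is an error
  expect_error(build_pileup(aligned(substr(ref, 1, 50), L - 10L), ref), "overrun")
})

test_that("SAM round trip preserves alignments and pileups", {
  set.seed(34)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  hs <- make_haplotype_set(600, 1, 0, 0, proportions = 1, seed = 12)
  sim <- simulate_reads(hs, coverage = 8, dmg = damage_model(0, 0, 0.5, 0), seed = 12)
  aln <- map_reads(sim$reads, hs$reference, sample_id = "sx")
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, hs$reference, "chr", f)
  back <- read_sam(f)
  expect_equal(back$name, aln$name)
  expect_equal(back$start, aln$start)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$seq, aln$seq)
  expect_equal(back$sample_id, aln$sample_id)
  pk_a <- build_pileup(aln, hs$reference)
  pk_b <- build_pileup(back, hs$reference)
  expect_identical(pk_a$counts, pk_b$counts)
})
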