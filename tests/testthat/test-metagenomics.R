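hits_df <- function(query, bitscore, taxid, identity = 99, evalue = 1e-20,
                    qcov = 100) {
  data.frame(query = query, subject = paste0("subj_", seq_along(query)),
             identity = identity, length = 50, qstart = 1, qend = 50,
             evalue = evalue, bitscore = bitscore, taxid = taxid, qcov = qcov,
             stringsAsFactors = FALSE)
}

test_that("naive LCA assigns singletons, merges top hits, and honours the top-percent boundary", {
  tree <- toy_taxonomy()
  cfg <- pipeline_config()
  ## one surviving hit -> its species
  a1 <- naive_lca(hits_df("q1", 100, "S1"), tree, cfg)
  expect_equal(unname(a1["q1"]), "S1")
  ## two hits within top 10% (91 >= 90): LCA = genus
  a2 <- naive_lca(hits_df(c("q1", "q1"), c(100, 91), c("S1", "S2")), tree, cfg)
  expect_equal(unname(a2["q1"]), "genusG")
  ## 89 falls outside the top 10%: assignment stays the best hit's species
  a3 <- naive_lca(hits_df(c("q1", "q1"), c(100, 89), c("S1", "S2")), tree, cfg)
  expect_equal(unname(a3["q1"]), "S1")
  ## pre-filters: low score / high e-value / low identity / low coverage all drop hits
  expect_length(naive_lca(hits_df("q1", 20, "S1"), tree, cfg), 0L)
  expect_length(naive_lca(hits_df("q1", 100, "S1", evalue = 1), tree, cfg), 0L)
  expect_length(naive_lca(hits_df("q1", 100, "S1", identity = 80), tree, cfg), 0L)
  expect_length(naive_lca(hits_df("q1", 100, "S1", qcov = 50), tree, cfg), 0L)
  expect_error(naive_lca(hits_df("q1", 100, "S9"), tree, cfg), "unknown taxon")
})

test_that("assignments are ancestors-or-self of every surviving hit and respect min-support", {
  tree <- toy_taxonomy()
  cfg <- pipeline_config(lca_min_support = 20)  # 20% of assigned queries
  ## 9 queries to S1, 1 query to S3: S3 at 10% fails support, moves to famF,
  ## then bac (still 10%) ... up to a supported ancestor or root
  h <- hits_df(c(paste0("q", 1:9), "q10"), 100,
               c(rep("S1", 9), "S3"))
  asg <- naive_lca(h, tree, cfg)
  expect_equal(unname(asg["q10"]), "root")
  expect_true(all(asg[paste0("q", 1:9)] == "S1"))

  ## ancestor-or-self invariant on random hit sets
  set.seed(81)
  cfg2 <- pipeline_config()
  species <- c("S1", "S2", "S3")
  for (i in 1:10) {
    n <- sample(1:4, 1)
    hh <- hits_df(rep("q", n), sample(80:100, n, replace = TRUE),
                  sample(species, n, replace = TRUE))
    a <- naive_lca(hh, tree, cfg2)
    best <- max(hh$bitscore)
    surviving <- hh$taxid[hh$bitscore >= 0.9 * best]
    for (tx in surviving) {
      anc <- tx
      ok <- FALSE
      while (TRUE) {
        if (anc == a[["q"]]) { ok <- TRUE; break }
        if (anc == "root") break
        anc <- tree$parent[[anc]]
      }
      expect_true(ok)
    }
  }
})

test_that("competitive filtering keeps reads the database cannot beat outside the genus", {
  tree <- toy_taxonomy()
  reads <- data.frame(name = c("r1", "r2", "r3", "r4"),
                      ref_bitscore = c(80, 80, 80, 80),
                      stringsAsFactors = FALSE)
  db <- rbind(hits_df("r1", 75, "S3"),       # ref wins outright
              hits_df("r2", 80, "S2"),       # tie, but same genus -> kept
              hits_df("r3", 85, "S3"),       # db wins, different family -> removed
              hits_df("r4", 85, "S1"))       # db wins but within genus -> kept
  out <- competitive_filter(reads, db, tree, "genusG")
  expect_setequal(out$name, c("r1", "r2", "r4"))
  ## reads with no database hit at all are retained
  out2 <- competitive_filter(data.frame(name = "r9", ref_bitscore = 10),
                             db, tree, "genusG")
  expect_equal(out2$name, "r9")
  ## raising the target to the root never shrinks the retained set
  out_root <- competitive_filter(reads, db, tree, "root")
  expect_true(all(out$name %in% out_root$name))
})

test_that("per-megabase normalization is plain division", {
  expect_equal(reads_per_mb(1000, 1e6), 1000)
  expect_equal(reads_per_mb(0, 5e6), 0)
  ## 310,000 reads on a 33.33-Mb genome: 9.3 thousand per Mb
  expect_equal(reads_per_mb(310000, 33.33e6) / 1000, 9.3, tolerance = 0.005)
  expect_error(reads_per_mb(10, 0), "positive")
})

test_that("summary-table arithmetic reproduces the published percentages exactly", {
  counts <- c(Bacteria = 18852, Mycobacterium = 6268, Eukaryota = 9333,
              Nannochloropsis = 5913, N_limnetica = 2223, Other = 1303)
  tab <- summary_table(counts, n_identified = 29488, n_analysed = 2e6)
  expect_equal(tab$I[tab$taxon == "Nannochloropsis"], 20.05)
  expect_equal(tab$I[tab$taxon == "Bacteria"], 63.93)
  expect_equal(tab$I[tab$taxon == "Mycobacterium"], 21.26)
  expect_equal(tab$I[tab$taxon == "N_limnetica"], 7.54)
  expect_equal(tab$A[tab$taxon == "Bacteria"], 0.94)
  expect_equal(tab$A[tab$taxon == "Nannochloropsis"], 0.30)  # see acceptance note
  ## rows sorted by N descending
  expect_equal(tab$taxon[1], "Bacteria")
  expect_true(all(diff(tab$N) <= 0))
  ## the I column over exclusive top-level categories + remainder sums to 100
  excl <- c(Bacteria = 18852, Eukaryota = 9333, Other = 1303)
  t2 <- summary_table(excl, 29488, 2e6)
  expect_lt(abs(sum(t2$I) - 100), 0.05)
  expect_error(summary_table(counts, 0, 10), "denominator")
  expect_error(summary_table(counts, 30000, 20000), "exceeds")
})

test_that("unique/shared mapping counts equal the set-algebra oracle", {
  expect_equal(unname(unique_mapping_crosstab(list(g1 = "a", g2 = "b"))$unique),
               c(1, 1))
  same <- unique_mapping_crosstab(list(g1 = c("a", "b"), g2 = c("a", "b")))
  expect_equal(unname(same$unique), c(0, 0))
  expect_equal(same$shared$n_shared, 2L)

  set.seed(82)
  ids <- sprintf("id%04d", 1:1000)
  sets <- list(gA = sample(ids, 400), gB = sample(ids, 300), gC = sample(ids, 200))
  got <- unique_mapping_crosstab(sets)
  for (g in names(sets)) {
    others <- unlist(sets[setdiff(names(sets), g)])
    expect_equal(unname(got$unique[g]), length(setdiff(sets[[g]], others)))
  }
  for (r in seq_len(nrow(got$shared))) {
    expect_equal(got$shared$n_shared[r],
                 length(intersect(sets[[got$shared$genome_a[r]]],
                                  sets[[got$shared$genome_b[r]]])))
  }
})

test_that("taxonomy and hit-table readers round-trip the TSV dialects", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child\tparent\trank\tname",
               "root\troot\troot\troot",
               "euk\troot\tsuperkingdom\tEukaryota",
               "S1\teuk\tspecies\tSpecies one"), tf)
  tree <- read_taxonomy(tf)
  expect_equal(tree$root, "root")
  expect_equal(lca_of(tree, c("S1", "euk")), "euk")

  hf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "subj", "99.0", "50", "0", "0", "1", "50", "101",
                   "150", "1e-20", "95.3", "S1", sep = "\t"), hf)
  hits <- read_hits(hf, query_lengths = c(q1 = 50L))
  expect_equal(hits$bitscore, 95.3)
  expect_equal(hits$taxid, "S1")
  expect_equal(hits$qcov, 100)
  ## cycle detection
  bad <- data.frame(child = c("root", "a", "b"), parent = c("root", "b", "a"))
  expect_error(taxonomy_tree(bad), "cycle")
})
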