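---
title: "Models and methods behind sedapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sedapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedapop)
```

`sedapop` analyses shotgun-sequenced sedimentary ancient DNA (sedaDNA) for
one abundant taxon: it reconstructs composite organellar genomes from a
mixed population's pooled reads, quantifies within-population allelic
variation, and bounds the number of haplotypes present using read-backed
phasing. This vignette is the package's own account of the models, the
tunable parameters, the numerical conventions it pins down, and the limits
of what its tests establish.

## The data-generating model the package assumes

Ancient sediment DNA is short (here 35–160 bp), chemically damaged, and
mixed across taxa and across conspecific lineages. The simulator
(`make_haplotype_set()`, `simulate_reads()`) states this world explicitly:

* **Haplotype mixture.** 1–4 equal-length organellar haplotypes at fixed
  proportions. Each planted variant site carries the reference base plus
  exactly one alternative, so transversion sites stay transversion-pure.
  Linked pairs of transversion sites (a configurable gap apart, within one
  fragment length) give the phasing signal the haplotype estimator needs;
  haplotypes receive pairwise-distinct two-site combinations, and every
  site varies in at least one haplotype.
* **Fragments.** Lengths are log-normal (location `log(mean_length)`,
  scale `spread`), rejection-truncated to [35, 160] bp. The literature on
  LGM-age lake sediments reports fragment bounds but no distribution; the
  log-normal with mean 65 bp and `spread` 0.25 is this package's stated
  default, config-exposed (`frag_mean_length`, `frag_spread`) because one
  of the two original samples is described only as having "shorter"
  fragments, without a number.
* **Damage.** Cytosine deamination is applied in read coordinates before
  reverse-complementing: C→T at 5′ distance z with probability
  `d5 * decay^z`, G→A at 3′ symmetric and independent (double-stranded
  library behaviour). Defaults `d5 = d3 = 0.3`, `decay = 0.5` reproduce the
  steeply decaying ~30% terminal signal typical of authentic LGM-age
  material. Uniform sequencing error (default 0.001) follows; base
  qualities are emitted consistent with it.
* **Not emulated:** PCR duplicates beyond exact copies, GC bias, indels
  (the variant analysis is substitution-only throughout), paired-end
  structure, and co-extracted DNA from other taxa. A green test therefore
  establishes correctness of the estimators under this stated world, not
  robustness to, e.g., mapping contamination from relatives — on real data
  that role is played by competitive filtering (`competitive_filter()`),
  which is tested on constructed instances.

## Read filtering

`dust_score()` pins the DUST variant: over every 64 bp sliding window,
`sum c_t (c_t - 1) / 2 / (w - 1)` with `c_t` the count of each overlapping
3-mer among the window's `w` valid triplets; N-containing triplets are
skipped, and reads over 50% N are removed as degenerate. Removal is strict
(`> 1`): a read scoring exactly the threshold is kept. A 35 bp homopolymer
scores 16.5; a sequence of all-distinct 3-mers scores 0. The brute-force
triplet oracle in the test suite defines this contract.

## Mapping, duplicates, pileup

The internal mapper is deliberately minimal: both orientations, exact
16-mer seeding at every query offset, full-length Hamming scoring, best
placement with ties broken to the lowest reference start then the plus
strand, and rejection above a 10% mismatch rate (`max_mismatch_rate`,
config-exposed since the original pipeline's aligner defaults are not
parameterised in print). It is ungapped by design — the simulator emits no
indels and the variant caller skips them — and real-data users can ingest
external SAM with `read_sam()` instead; both routes produce identical
pileups for identical placements.

Duplicate removal has two senses, matching degraded single-end libraries:
`remove_exact_duplicates()` collapses identical (orientation-normalised)
sequence strings to one uniformly random copy — such duplicates can sit at
different coordinates — and is re-run per replicate with its own labelled
RNG substream; `remove_coordinate_duplicates()` collapses reads sharing
(start, strand, length), keeping the highest mean base quality
(deterministic; length stands in for the outer coordinate of merged
fragments).

## Damage profiling and PMD scores

`damage_profile()` reports C→T frequency by 5′ distance and G→A by 3′
distance over the first 25 positions (capped at `profile_length_cap`,
160 bp), computed after strand normalisation. `pmd_score()` pins the
post-mortem-damage likelihood ratio: with `D(z) = d * decay^z` and
per-substitution error `e = 10^(-q/10)`, a read position over reference C
at 5′ distance z contributes `log((D + (1 - D) e) / e)` if T is observed,
`log(1 - D)` if C is observed, 0 otherwise; symmetric for reference G at
the 3′ side; other reference bases are uninformative. Priors `d = 0.3`,
`decay = 0.5` are config-exposed (`pmd_d`, `pmd_decay`). CpG-specific
treatment is deliberately omitted (not described in the source pipeline,
so not guessed). The threshold `PMD >= 3` defines the damaged-only subset.

## Composite consensus

`majority_consensus()` takes the highest-count base per covered column;
ties prefer the current seed base when it is among the leaders (a
conservative, reference-stable choice the original description leaves
open), otherwise the lexicographically smallest base. Uncovered columns
take the seed base (`reference_fill`, for complete reconstruction from a
close seed) or `N` (`no_fill`, for diverged seeds whose mapping rate is
too low to trust fill-in). "Repeated until the consensus could no longer
be improved" is pinned as exact sequence identity between successive
iterations, with a `max_iter = 10` safety; a non-convergent or
zero-mapping run is returned flagged rather than raised. De novo assembly
of coverage gaps is out of scope; gaps are reported as intervals and
`splice_patches()` accepts externally assembled patch sequences by exact
flanking anchors.

## Variant analysis

`call_variants()` pins a simple, oracle-checkable statistic in place of a
full genotype-likelihood model: alleles enter a site with at least 2
reads; a site needs ≥2 such alleles, depth at least `min_cov`, and quality
at least `min_qual` (default 30), where quality is the Phred-scaled exact
binomial tail probability that the minor-allele count arose from
base-calling error at the column's mean quality-implied rate. "Half the
average coverage" is pinned as mean depth over all positions including
zeros, halved and floored (`coverage_cutoff()`).

`apply_rare_allele_floor()` then removes alleles below 0.1 of the site
(strict `<`; proportions are reported raw, not renormalised, with removals
flagged) and re-evaluates the transversion flag on the survivors. The
ordering matters and is a deliberate design decision: terminal deamination
routinely deposits a two-to-three-read transition allele on top of a
genuine transversion site; evaluated raw, such a site is multiallelic with
a transition pair and the transversion-only restriction would discard it.
Applying the floor first — the original pipeline's own noise device —
restores the site. The test suite's haplotype-recovery properties exercise
exactly this interplay.

`split_high_low()` assigns the allele present in the composite genome to
the high-frequency haplogroup set regardless of its frequency — membership
is identity with the reconstructed reference, not majority — and
everything else to the low set; a site whose alleles exclude the composite
base is flagged and contributes to the low set only.
`allele_proportions()` maps the reads separately against both haplogroup
consensus sequences to avoid reference bias, merges, removes exact then
coordinate duplicates, re-calls, and reports per-site and genome-wide mean
alternative proportions for each of `n_dedup_replicates = 5` replicates.
`damage_restricted_recall()` repeats the calling on the PMD-filtered subset
with the relaxed thresholds (quality 3, depth 3) appropriate to its lower
coverage and reports the fraction of original transversion sites
recovered.

## Minimum haplotype count from read linkage

Transversion-site positions pooled across samples are clustered by greedy
left-to-right chaining while the cluster span stays within 35 bp
(`window_span`); the greedy rule is the pinned contract — alternative
clusterings are not enumerated. Scoring is per sample: a read contributes
to a window only if its aligned span covers every cluster position; its
allele combination is its concatenated bases there (combinations with
non-ACGT bases excluded). Combinations with fewer than 3 spanning reads or
below 15% of spanning reads are removed — strictly, so exactly 3 reads and
exactly 15% survives. A window with k surviving combinations demonstrates
at least k haplotypes; the overall estimate is the maximum over windows
and samples, and per-sample means over scorable windows are reported. The
estimate is a lower bound by construction (the filters only remove), which
the property tests verify across seeds; with all mixture proportions at
least 0.20 and 100× coverage the true K is recovered in ≥95% of seeded
runs. Windows are scored on each dedup replicate's read set where
replicates are in play; the per-replicate spread is reported rather than
averaged away.

## Taxonomic summarisation

`naive_lca()` filters tabular hits on bitscore (≥35), e-value (≤1e−5),
identity (≥95%), and query coverage (≥95%), keeps hits within 10% of the
best bitscore (inclusive boundary: `bitscore >= 0.9 * best`), assigns the
LCA of the survivors, and then re-assigns taxa holding under 0.01% of
assigned queries to their parents until supported (the "move up"
disposition; the source states the threshold but not the disposition).
Because the 12+1-column tabular hit format carries no query length,
`read_hits()` computes coverage only when query lengths are supplied and
otherwise sets it to 100, leaving the filter inert — stated here rather
than silently guessed. The min-support tally is computed on the merged
per-sample hit set. `summary_table()` performs the percentage arithmetic
(I = share of identified, A = share of analysed, two decimals; the
"analysed" denominator is always passed explicitly, never inferred), and
`competitive_filter()` retains reference-mapped reads unless the general
database matches as well or better *and* places the read outside the
target genus.

## Reproducibility

All randomness descends from one master seed through labelled substreams
(`substream_seed(seed, stage, index)`), so each replicate is individually
reproducible and a pipeline run is byte-identical under a repeated seed —
asserted directly in the test suite. Simulation sizes in the tests are
scaled to desk budgets (e.g. ~10,000-read damage profiles instead of
50,000; the binomial standard errors stay several-fold inside the asserted
tolerances).

## Known limitations

The mapper is ungapped and desk-scale; use external alignments for real
data. The variant quality model is a pinned binomial statistic, not a
genotype-likelihood caller; absolute quality values are comparable within
this package only. Haplotype counts are window-local minima — linking
windows into full-length haplotypes requires a reference panel and is out
of scope. The LCA implementation assumes a single-rooted, cycle-free
taxonomy edge list.
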