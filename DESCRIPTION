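Package: sedapop
Title: Population Genomics from Sedimentary Ancient DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for environmental palaeogenomics from degraded,
    multi-taxon sedimentary ancient DNA (sedaDNA). Implements read
    filtering (length and DUST low-complexity), a desk-scale ungapped
    mapper, duplicate removal, cytosine-deamination damage profiling and
    post-mortem-damage (PMD) read scoring, iterative reference-guided
    reconstruction of composite organellar palaeogenomes,
    transversion-only variant calling with high/low-frequency haplogroup
    consensus splitting, replicated allele-proportion estimation, a
    read-linkage minimum-haplotype-count estimator, and naive
    lowest-common-ancestor taxonomic assignment from tabular similarity
    hits. Includes a fully parameterised ancient-DNA read simulator with
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
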