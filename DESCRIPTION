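Package: somavar
Title: Structural and Nucleotide Variation in Mutagenized and Transgenic Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing genome-wide structural variation and single
    nucleotide substitutions across plant genotypic classes (standing
    cultivar variation, fast-neutron mutants, and transgenic lines).
    Implements array-CGH copy-number segmentation by recursive binary
    splitting with a permutation acceptance test, UpCNV/DownCNV
    classification against calibrated log2-ratio thresholds, removal of
    intra-cultivar heterogeneity shared across plants, and gene-overlap
    accounting; filtering of multi-sample genotype calls down to
    substitutions that are homozygous and private to one individual;
    T-DNA insertion-site mapping from construct-anchored read pairs with
    orphaned mates, including detection of insertion-adjacent deletions
    from read depth and pair spacing; and breakpoint-junction resolution
    reporting deletion size, microhomology, and filler sequence. A
    synthetic-data module generates probe tracks, genotype cohorts,
    paired-end read sets and junction sequences with known ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
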