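Package: poolER
Title: Pooled Time-Series Genomics for Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of pooled whole-population sequencing (pool-seq) time
    series from evolve-and-resequence experiments with clonal organisms, built
    around a replicated Chlorovirus-Chlorella chemostat coevolution design.
    Provides artifact filtering of pooled variant calls (exact binomial
    constancy test with FDR correction, missing-data and batch-wide
    polymorphism rules), expected-heterozygosity diversity, effective selection
    coefficients from allele-frequency trajectories, cross-replicate
    repeatability, a codon-level SNP effect classifier with an exhaustive
    all-possible-mutations null spectrum, a per-ORF variable-site enrichment
    scan (Fisher's exact test with Holm correction), and a clonal
    Wright-Fisher forward simulator with bottleneck demography, pooled
    sequencing noise and injected artifact variants that generates inputs
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
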