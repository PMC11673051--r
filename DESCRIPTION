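Package: bovintro
Title: Selection Scans and Adaptive-Introgression Detection for Bovine
    Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for population-genomic analysis of
    cattle resequencing data: diversity and structure statistics (windowed
    nucleotide diversity, heterozygosity and inbreeding F, runs of
    homozygosity, LD decay, p-distance neighbor-joining trees, PCA),
    four-way selection scans (pi, Tajima's D, Weir-Cockerham FST, XP-EHH)
    with empirical-tail candidate regions, and an adaptive-introgression
    stack (Patterson's D with block jackknife, windowed U statistic,
    window-based local-ancestry tracts, incomplete-lineage-sorting tract
    probability filtering, per-sample introgression ratios, and region-level
    haplotype/tree confirmation). Ships a haplotype-mosaic simulator that
    emits VCF plus truth-tracked introgressed tracts and sweeps so every
    stage is verifiable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
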