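Package: refbias
Title: Reference Bias and Archaic Introgression Scans for Population Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the choice of reference assembly shapes
    population-genomic inference, and scans for archaic introgression.
    Implements frequency-based ABBA-BABA statistics (Patterson's D and the
    modified f_d) in sliding windows with putative-introgression-region
    calling, detection of reference-specific mapping regions from per-base
    depth, depth-scaled presence/absence genotyping of large insertions with
    population allele frequencies, per-site and windowed Weir-Cockerham Fst
    with empirical outlier p-values, structural-variant heterozygosity
    windows emitted as GFA bubble graphs, pairwise alignment p-distance, and
    the correlation between mapping performance and genetic distance. A
    self-contained simulator generates genotype matrices with planted
    introgression tracts, depth tracks with planted features, and mapping
    statistics with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
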