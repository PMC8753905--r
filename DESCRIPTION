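Package: tadrisk
Title: TAD-Border Enrichment Analysis of Disease-Associated SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Genome-wide test of whether disease-associated SNPs are
    preferentially located in the borders of topologically associating
    domains (TADs). Calls TADs from Hi-C contact matrices with an
    insulation-minimum sliding-window algorithm scanned over a range of
    window sizes, extracts 20-kb TAD borders, tests per-disease
    hypergeometric enrichment of GWAS SNPs in borders under genome-based
    and SNP-based null models with Benjamini-Hochberg correction and a
    majority-over-k rule, compares cancers with non-cancer diseases by
    Fisher's exact test, and quantifies clustering in SNP-based diseasome
    networks with network-coherence z-scores. A synthetic-data generator
    plants TAD partitions and border-enriched disease catalogs so the
    whole pipeline can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
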