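Package: crossreg
Title: Cross-Species Projection, Filtering and Variant Scoring of
    Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects regulatory regions (promoters, enhancers,
    transcription factor binding sites) between genome assemblies through
    UCSC pairwise alignment chains with minMatch coverage thresholds,
    strict reciprocal validation and a multi-mapping rescue round for
    duplicated loci; merges projected datasets into a universal dataset
    with annotation provenance; filters it with a species-specific
    enrichment cascade (CAGE, H3K27Ac, RNA-seq, gapped k-mer model score,
    annotation count, conservation, motif counts) assessed by
    enhancer/promoter density ratios; and scores noncoding variants with a
    gapped k-mer sequence classifier via the deltaSVM statistic. Includes
    a seeded synthetic-genome generator with ground-truth chains, planted
    regulatory regions, signal tracks and variants for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
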