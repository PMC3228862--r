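Package: interAlu
Title: In-Silico Inter-Alu PCR Capture Prediction and Paired Tumor/Normal
    Variant Post-Processing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the genomic footprint capturable by inter-Alu PCR with
    Alu-consensus primers. Represents head-type (H) and tail-type (T) primers,
    finds mismatch-tolerant binding sites on a genome sequence or places them
    from repeat annotations, enumerates convergent site pairs as candidate
    amplicons within a product-size window, and accounts the merged capturable
    footprint and inter-Alu gap structure. Also computes targeted-capture
    summary statistics (depth-filtered regions, genic and candidate-gene
    enrichment, per-chromosome correlation with Alu counts, window density
    tracks, paired-sample overlap) and applies rule-based post-processing to
    paired control/tumor variant calls: genotype classification by
    non-reference read frequency, somatic SNV and LOH calling, novelty
    filtering against a known-SNP list, transition/transversion tallies,
    indel size partition, and fixed-window SNV hotspot detection. A synthetic
    data module simulates genomes with planted Alu copies and paired variant
    tables with known truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Alignment, SNP, SomaticMutation, Coverage
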