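Package: nsLTPscan
Title: Genome-Wide Identification and Characterization of Plant
    Non-Specific Lipid Transfer Proteins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies and characterizes plant non-specific lipid
    transfer protein (nsLTP) gene families from a proteome. Detects the
    eight-cysteine motif (8CM) with a deterministic spacing grammar,
    applies a candidate filter cascade (essential cysteines, N-terminal
    signal sequence, similarity to protease inhibitors and storage
    proteins, hybrid proline-rich proteins), computes mature-protein
    molecular mass and isoelectric point, classifies proteins into
    nsLTP types (1, 2, C, D, E, G, X) by GPI-anchor presence and
    pairwise identity, analyses genome context (chromosome
    distribution, tandem duplicate arrays, reciprocal-best-hit
    orthology, collinearity), classifies organ expression and calls
    differentially expressed genes from count matrices, and scans
    promoters for stress-related cis-elements. Ships a transcription of
    the published 89-member cabbage (Brassica oleracea) nsLTP catalog
    and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
biocViews: Annotation, SequenceMatching, GenomeAnnotation,
    DifferentialExpression, MotifDiscovery
Config/testthat/edition: 3
RoxygenNote: 7.3.3
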