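Package: shfgrn
Title: Hedgehog-Dependent Target Gene Inference in the Second Heart Field
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor chromatin occupancy with
    loss-of-function transcriptional profiling to nominate direct target
    genes of Hedgehog/GLI signaling in cardiac progenitors. Provides a
    SAM-type permutation differential-expression engine with generalized-log
    normalization and Storey q-values, peak-to-gene annotation under a
    100-kbp window / nearest-TSS rule, Fisher-exact enrichment with
    cross-product odds ratios, IUPAC consensus-motif scanning with
    heterotypic adjacency pairing (GLI + T-box), and a synthetic-data
    generator that plants known differential expression, peak placement and
    motif pairs so every stage has a ground-truth test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'expression.R'
    'integrate.R'
    'io.R'
    'motifs.R'
    'peaks.R'
    'pipeline.R'
    'shfgrn-package.R'
    'synthetic.R'
    'utils.R'
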