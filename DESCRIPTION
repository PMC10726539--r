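Package: fusionWGS
Title: Validation of RNA-Seq Fusion Transcripts in Matched Whole-Genome
    Sequencing Data and Machine-Learning Filtering of Fusion Calls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates gene-fusion transcripts predicted from RNA-Seq
    (FusionCatcher- and Arriba-style call tables) at the DNA level using
    matched whole-genome sequencing alignments: discordant read pairs are
    extracted from fusion-partner search regions and genomic breakpoints are
    localized from locally re-aligned soft-clipped read ends. Validated
    fusions serve as ground truth for a gradient-boosted classifier that
    predicts true-positive fusions from RNA-only features, benchmarked
    against classical confidence/read-support filters. Downstream analyses
    cover junction microhomology versus simulated control breakpoints,
    breakpoint-flanking depth-ratio profiles, genomic-context annotation,
    exon-level expression contrasts, kinase-fusion classification, and
    binomial (sampling-with-replacement) gene-set over-representation. A
    deterministic simulator generates a toy genome, planted fusions with
    configurable junction microhomology and segmental amplification,
    paired-end WGS reads as SAM, and caller-style output tables, so the
    whole pipeline is exercisable end to end without external data.
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
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    xgboost,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, StructuralVariation, Classification
RoxygenNote: 7.3.3
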