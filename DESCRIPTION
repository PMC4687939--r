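Package: rifpipe
Title: Regulatory Impact Factor Analysis for Two-Genotype Muscle
    Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the computational core of a
    two-genotype (purebred Iberian versus Iberian x Duroc) muscle
    transcriptome analysis: FPKM normalization and three-criterion
    differential-expression filtering, Regulatory Impact Factor (RIF1/RIF2)
    discovery of candidate transcription regulators with a bootstrap null
    distribution for their z-scores, efficiency-corrected qPCR validation
    through a joint linear mixed model with concordance checking against
    RNA-Seq fold changes, fixed-versus-segregating variant classification
    with toy coding-consequence annotation, and fatty-acid composition
    indices. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is exercisable and testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
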