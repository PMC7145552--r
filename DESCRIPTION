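Package: TEcisReg
Title: Transposable Elements as a Source of Transcription Factor Binding Sites
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of transposable-element (TE) derived transcription
    factor binding sites from ChIP-seq peak summits and RepeatMasker
    annotation. Provides family-level binomial enrichment of TE-resident
    summits against genomic fractions, projection of summits onto TE
    subfamily consensus coordinates with copy-coverage-normalized binding
    profiles and positional uniformity tests, PWM motif scanning with exact
    p-values, conservation and accessibility meta-profiles with random-TE
    controls, chain-based cross-species liftover and clade-of-origin dating
    of binding events, factor colocalization tests within TE copies,
    genome-wide density scans of factor-bound TEs, and a self-consistent
    synthetic data generator with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, FunctionalGenomics, Transcription, Annotation
RoxygenNote: 7.3.3
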