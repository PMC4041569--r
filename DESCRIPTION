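Package: androTF
Title: Promoter Binding-Site Density Filtering for Transcription Factor
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nominates transcription factors that coordinate prostate gland
    adaptation to androgen deprivation. Implements thresholding of
    multi-condition differential expression, exclusivity (Venn)
    partitioning, selection of a top-regulated gene panel, Match-style
    position weight matrix scanning of proximal promoters with
    information-vector weighting and per-matrix cutoff calibration,
    binding-site density filtering against internal-control promoters,
    intersection with a network-derived factor list, a
    correlation-distance minimum spanning tree of candidate expression
    across tissues, and delta-delta-Ct qPCR fold-change quantification
    with quartic trend fitting. A synthetic-data module generates every
    pipeline input with known ground truth so each stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcription, MotifAnnotation, GeneExpression, Software
RoxygenNote: 7.3.3
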