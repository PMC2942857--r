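Package: ms4anchors
Title: Anchor-Point Detection for Multiple Sequence Alignment via
    N-Local Decoding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects anchor points (partial alignment columns) for multiple
    sequence alignment. Sequence positions are clustered by shared length-N
    word contexts (N-local decoding), combined across word lengths in a
    partition tree from which non-ambiguous columns spanning a minimum
    number of sequences are selected (the MS4 rule), and order
    inconsistencies are removed with a succession-graph algorithm: a
    weight-threshold feedback-arc-set heuristic yields a DAG, and
    per-sequence longest paths decide which column occurrences to keep, so
    that the surviving columns admit a multiple alignment. Columns are
    exported as pairwise anchor segments in DIALIGN, BALLAST and T-Coffee
    library formats. Also provides sum-of-pairs, total-column and
    specificity scoring of a test alignment against a reference, and a
    seeded planted-motif fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Alignment, MultipleSequenceAlignment, SequenceMatching
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'sitespace.R'
    'nld.R'
    'ms4.R'
    'consistency.R'
    'anchors.R'
    'evaluate.R'
    'ms4anchors-package.R'
    'synthetic.R'
    'pipeline.R'
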