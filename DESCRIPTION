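Package: actseg
Title: Segmentation of Long-Term Activities from Wrist-Worn Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments multi-day triaxial accelerometer recordings into
    long-term activities (working, commuting, having dinner, ...). Raw
    signals are smoothed, windowed and summarised into 12 statistical
    features, vector-quantized against a k-means codebook into sequences of
    discrete motion primitives, and decoded with the Viterbi algorithm on a
    hidden Markov model or a linear-chain conditional random field whose
    feature functions add k-mer (sequence pattern) information. A
    minimum-run-length (k-minimum-consecutive-states) constraint encodes the
    minimum lifespan of each activity. An optional subclassing stage detects
    intra-class fragmentation with cluster validity indices (silhouette, PBM,
    generalized Dunn) and splits fragmented classes when a cross-validated
    accuracy gate approves. Includes a seeded generator of labeled synthetic
    multi-day recordings and a leave-one-day-out evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'preprocess.R'
    'quantize.R'
    'models.R'
    'decode.R'
    'oracle.R'
    'indices.R'
    'naivebayes.R'
    'subclass.R'
    'evaluate.R'
    'synthgen.R'
    'config.R'
    'io.R'
    'actseg-package.R'
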