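Package: topodrugQSPR
Title: Degree-Based Topological Indices and QSPR Regression for Drug Molecules
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes ten degree-based topological indices (first and second
    Zagreb, harmonic, forgotten, Schultz second, atom-bond connectivity,
    Randic, sum-connectivity, geometric-arithmetic and hyper-Zagreb) from
    hydrogen-suppressed molecular graphs or their edge-degree partitions, and
    models physicochemical properties of small drug molecules by single-
    predictor linear, quadratic and logarithmic least-squares regression.
    Ships the complete nine-drug reference dataset (edge-degree partitions,
    eight physicochemical properties, reference index values and regression
    summaries), a seedable generator of chemistry-like random graphs with
    simulated property responses, and a pipeline that rebuilds the full
    index table, coefficient-of-determination grids, best-predictor fit
    statistics and model-form comparison, flagging cells where the bundled
    reference values are internally inconsistent.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'molgraph.R'
    'indices.R'
    'referenceData.R'
    'regression.R'
    'synthetic.R'
    'pipeline.R'
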