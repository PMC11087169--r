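Package: aptscore
Title: Plan-Quality Scoring and Course Simulation for Adaptive Proton Therapy
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dosimetric quality analysis of adaptive proton therapy
    courses in head-and-neck radiotherapy. Computes cumulative dose-volume
    histograms and clinical endpoint metrics (V100, D98, Dmax, Dmean, D0.03cc)
    from voxel dose grids and structure masks, implements a modified ProKnow
    piecewise-linear plan-quality scoring system (capped at 7, unbounded
    negative tails, serial-organ step penalties) calibrated by least squares
    from published endpoint/score pairs, and simulates fraction-wise treatment
    courses with anatomy drift, setup error and none/offline/online adaptation
    policies so that nominal, offline and online courses can be compared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'aptscore-package.R'
    'io.R'
    'scoring.R'
    'calibrate.R'
    'dvh-engine.R'
    'synthetic.R'
    'course.R'
    'cli.R'
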