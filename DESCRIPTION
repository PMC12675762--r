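Package: spinecurve
Title: Radiation-Free Intraoperative Spinal Alignment Estimation from Sparsely
    Tracked Vertebrae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intraoperative spinal alignment without imaging by
    modelling the spine as a chain of rigid vertebrae whose in-plane curvature
    is captured with Bezier curves anchored at two optically tracked
    vertebrae. Provides rigid-pose bookkeeping relative to the superior
    tracked vertebra, two curve-estimation constructions (endplate normals
    with or without initial CT spacing), two untracked-vertebra placement
    rules (height fraction, chord perpendicular), two orientation corrections
    (superior-tangent, intermediate endplate vector), pairwise Cobb-style
    endplate-angle tables with baseline/simulated/delta columns, RMSE and
    absolute-error summaries, the eight evaluation-method compositions, a
    synthetic spine-phantom generator with ground truth, and an embedded
    porcine proof-of-concept measurement table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
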