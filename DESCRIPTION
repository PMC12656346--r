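Package: dmsm
Title: Dynamic Motion Similarity Measurement for Golf Swing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Phase-aware similarity analysis of pose-estimated golf swings.
    Segments side-view 2D keypoint sequences into the seven canonical swing
    phases (address, takeaway, half, top, impact, release, finish) from
    kinematic cues, normalizes skeletons by body scale, and scores swing
    similarity by integrating absolute trajectory differences within each
    phase (DMSM). Includes dynamic-time-warping, Euclidean, phase-wise
    Pearson, and joint-angle baselines, spine-angle biomechanical
    diagnostics, a synthetic swing generator with ground-truth phase
    boundaries, and a batch evaluation harness with separation statistics
    (Welch t, Shapiro-Wilk, Cohen's d, bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
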