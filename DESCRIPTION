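Package: strainloops
Title: Strain-Volume and Strain-Area Loop Analysis with Reliability Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of left-ventricular strain-volume and
    right-ventricular strain-area loops from per-frame speckle-tracking
    echocardiography curves. Provides a physiologically shaped single-cycle
    simulator with a hierarchical subject/scan/observer/analysis error model,
    delimited trace and study-manifest input/output, loop geometry construction
    on a common volume grid, the ten loop-derived parameters (systolic and
    diastolic slopes, peak strain, diastolic uncoupling, loop area, peak
    strain to end-diastolic size ratio), and an agreement-statistics battery:
    single-rater absolute-agreement intraclass correlation ICC(A,1) with
    F-based confidence intervals and Koo-Li classification, Bland-Altman
    limits of agreement with proportional-bias checks, and exact or
    tie-corrected Wilcoxon signed-rank tests. A study pipeline orchestrates
    intra-observer, inter-observer and test-retest reliability designs with
    matched-cycle and heart-rate sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
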