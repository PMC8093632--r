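Package: hexacoord
Title: Inter-Leg Coordination Analysis for Hexapod Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinematic and statistical analysis of inter-leg coordination in
    freely walking hexapods, from marker-based motion capture through
    step-cycle segmentation to circular-statistics phase coupling and
    balanced-bootstrap cohort comparison. Includes a six-leg oscillator
    walker simulator with Cruse-rule (rule 1 and rule 2) coupling and a
    connective-lesion switch for generating ground-truthed synthetic trials,
    a threshold/nearest-neighbour marker tracker for rendered image stacks,
    body-centred protraction/retraction angle computation, AEP/PEP event
    detection, per-animal mean phase vectors with Watson-Williams and
    two-sample Kuiper tests, and two-step balanced bootstrap estimates of
    cohort medians with CI-overlap significance and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    signal,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
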