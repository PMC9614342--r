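Package: gaitmood
Title: Emotion Effects on Gait from Marker-Based Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how felt emotion shapes walking
    style in marker-based optical motion capture of subjects walking freely
    along circular paths. Detects steps from the inter-foot distance signal,
    computes a signed walking-straightness statistic from consecutive step
    vectors, extracts 24 body-part angles from a 37-marker set, aggregates
    angle means and standard deviations within seven straightness bins, and
    runs the emotion-effect statistics: one-way ANOVA with Tukey HSD
    follow-up, multi-factor ANOVA of arm-swing magnitude on emotion,
    curvature, arm side and gender, and per-emotion linear regressions of
    arm swing on signed path curvature. A synthetic gait cohort generator
    with controllable emotion effects, marker dropout and non-gait arm
    artifacts makes every stage testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
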