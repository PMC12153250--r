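Package: consistenrich
Title: Consistency-Based Multiplicity Adjustment for Enrichment Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Design and analysis of confirmatory enrichment trials that test
    a treatment in both the overall population and a biomarker-positive
    subgroup. Implements a joint (intersection) test whose rejection region
    is shaped by cross-subgroup consistency thresholds: the subgroup claim
    requires the marker-negative complement to retain a fraction b of the
    subgroup effect, and the overall claim requires each subgroup to retain
    a fraction k of the overall effect. Provides Monte-Carlo calibration of
    k to control the family-wise type I error, a deterministic quadrature
    oracle for the rejection-region probability, closed-testing claims for
    the individual hypotheses, benchmark procedures (Bonferroni, Dunnett,
    fixed-sequence, and consistency-constrained variants), disjunctive power
    simulation, and rejection-region / power plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
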