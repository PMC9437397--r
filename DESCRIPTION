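Package: sehra
Title: Planning and Validation of School Eye Health Rapid Assessment
    Cluster Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning school-based eye health cluster surveys:
    sample-size calculation for prevalence estimation under a cluster
    design (design effect, non-participation inflation, achievable
    precision, design-effect sensitivity tables), two-stage
    probability-proportionate-to-size systematic sampling over a school
    enrollment frame with equal-probability selection of children,
    cluster-level prevalence estimation with empirical design effects,
    and a Monte-Carlo harness that validates the design's statistical
    contract (design effect, confidence-interval coverage, relative
    precision) on synthetic beta-binomial school populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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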