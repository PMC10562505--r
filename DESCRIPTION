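Package: slncea
Title: Cost-Effectiveness of Sentinel Lymph Node Biopsy Tracer Agents in
    Early Oral Cavity Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model comparing technetium-99m
    tilmanocept with technetium-99m sulfur colloid as radiotracer agents for
    sentinel lymph node biopsy in early-stage (T1/T2, cN0) oral cavity
    squamous cell carcinoma. Provides a validated parameter container with
    the published base case built in, a four-branch diagnostic decision tree,
    a five-state (NED, local recurrence, nodal recurrence, distant
    metastasis, dead) annual-cycle cohort engine with discounted cost and
    quality-adjusted life-year accrual, incremental cost-effectiveness and
    net-monetary-benefit arithmetic with dominance classification, one-way
    and two-way deterministic sensitivity analyses with bisection-based
    decision-threshold search, an individual-level microsimulation used as an
    independent stochastic oracle for the cohort engine, and a generator of
    structurally valid random parameter sets for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
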