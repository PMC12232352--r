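Package: diamicro
Title: Individual-Level Microsimulation of Type 2 Diabetes Treatment
    Pathways and Complications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time (90-day quarter) individual-level microsimulation
    of type 2 diabetes progression after second-line glucose-lowering
    treatment.  Generates synthetic baseline cohorts from marginal summaries
    coupled by a Gaussian copula, simulates quarter-resolution treatment
    pathways (persistence, switching, administrative censoring), advances
    nine clinical risk factors through configurable autoregressive risk
    equations with additive drug-class effects, computes per-quarter
    probabilities and cumulative incidences of diabetes complications,
    supports hold-out calibration with additive recalibration offsets, and
    contrasts counterfactual second-line treatments (sulphonylureas, DPP4
    inhibitors, SGLT2 inhibitors) on 5-year outcomes with normal-based
    confidence intervals, overall and by baseline cardiovascular disease
    status.
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
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
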