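Package: acicea
Title: Cost-Effectiveness Modelling of Adoptive Cellular Immunotherapy in
    Metastatic Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for trial-based cost-effectiveness analysis
    of adoptive cellular immunotherapy added to XELOX/bevacizumab in
    metastatic colorectal cancer. Provides a synthetic trial emulator
    calibrated to published medians and hazard ratios, Kaplan-Meier tools
    including Guyot-style pseudo individual-patient-data reconstruction from
    digitized survival curves and numbers at risk, parametric survival
    fitting and information-criterion ranking across seven standard
    families, a three-state (progression-free, progressed, death) Markov
    cohort model on 21-day cycles, a costing and utility layer producing
    discounted costs, QALYs and ICERs, one-way and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, willingness-to-pay
    indexed price inversion, and horizon and distribution cross-validation
    scenario grids.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
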