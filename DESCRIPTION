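Package: hipcea
Title: Cost-Utility Analysis of Robotic Arm-Assisted Versus Manual Total
    Hip Arthroplasty
Version: 0.1.0
Authors@R:
    person("hipcea", "maintainers", email = "maintainers@hipcea.invalid",
           role = c("aut", "cre"))
Description: Deterministic cost-utility model comparing robotic
    arm-assisted total hip arthroplasty (rTHA) with manual THA (mTHA) in a
    UK setting: QALY accrual from an annual EQ-5D utility uplift with
    mortality/revision diminution and per-year discounting over 10-year
    and lifetime horizons, amortisation of the fixed robot cost by annual
    case volume, incremental cost-effectiveness ratios with volume sweeps,
    sensitivity and willingness-to-pay threshold checks. Includes a
    synthetic patient-cohort generator with the covariate structure of the
    motivating study (truncated-normal covariates, ceiling-censored
    postoperative utility) and the statistical pipeline that estimates the
    covariate-adjusted utility uplift by ordinary least squares, plus
    group comparisons and a two-sample power calculation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
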