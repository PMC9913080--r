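Package: bcscreen
Title: Natural-History Microsimulation of Breast Cancer Screening Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous tumour-growth microsimulation of invasive breast
    cancer for evaluating mammography screening policies. Simulates each
    woman's latent disease course (age at onset from a two-stage clonal
    expansion model, exponential tumour growth with gamma-distributed
    inverse growth rates, volume-proportional hazard of symptomatic
    detection, negative-binomial lymph-node involvement), superimposes
    screening programmes with a logistic size-dependent test sensitivity,
    resolves competing screen detection, symptomatic detection and
    other-cause death, and tallies programme-level outcomes: case
    categories, overdiagnosis, stage shift, lead time, survival
    differences and life-expectancy gain per mammogram, with
    parameter-uncertainty intervals by multivariate-normal propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
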