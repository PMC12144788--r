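Package: cfturnover
Title: Temporal Turnover of Cystic Fibrosis Lung Microbiota Across
    Pulmonary Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying temporal turnover in longitudinal airway
    microbiota time series from people with cystic fibrosis, and for relating
    turnover to clinical course across a pulmonary exacerbation (PEx).
    Implements species-time relationships (STRs) built with the moving-window
    richness accumulation method and fitted with the power model S = c*T^w;
    chronic/intermittent colonization classification by temporal persistence
    (a modified Leeds criterion) with persistence-abundance regressions;
    power-law models of cumulative absolute lung-function change
    (dFEV1 = a*T^b); sliding five-timepoint quadrat profiles of local w and b;
    threshold-based estimation of PEx onset lead time before treatment start;
    cohort-level rank tests and regressions; and a seeded synthetic cohort
    generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
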