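Package: spirok
Title: Potassium Homeostasis QSP Modelling and Bayesian Forecasting of
    Plasma Potassium under Spironolactone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A mechanistic (quantitative systems pharmacology) model of renal
    potassium handling with aldosterone feedback and spironolactone/canrenone
    pharmacokinetics, together with the analysis workflow needed to run it
    against inpatient electronic-health-record style data: local and eFAST
    global sensitivity analysis, collinearity-based identifiability analysis,
    inter-individual variability estimation, sequential maximum-a-posteriori
    (Bayesian) forecasting of next-day potassium trajectories, fold-error
    performance metrics, and a synthetic inpatient cohort generator for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    data.table
Config/testthat/edition: 3
NeedsCompilation: yes
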