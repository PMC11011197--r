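Package: nomcea
Title: Patient-Perspective Cost-Effectiveness of Organ Preservation in
    Locally Advanced Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Six-state Markov cohort model and microsimulation comparing
    total neoadjuvant therapy with non-operative management ("watch and
    wait") against chemoradiotherapy plus radical resection for locally
    advanced rectal cancer, costed from the patient perspective under
    German statutory health insurance rules. Includes an out-of-pocket
    cost model (co-payments with exemption limits, driving expenses,
    care supplements, loss of income), QALY accounting with annual
    discounting, incremental cost-effectiveness and net-monetary-benefit
    computation, one-way threshold sensitivity analysis, demographic
    derivations from age-stratified incidence, and a synthetic survey
    cohort generator for model checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
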