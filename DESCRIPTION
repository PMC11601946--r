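Package: chamberomics
Title: Indirect Calorimetry and Metabolome Analysis for Crossover Chamber Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts minute-level whole-room indirect calorimetry (VO2/VCO2)
    and 24-hour urinary nitrogen into 24-hour energy expenditure, respiratory
    quotient, nonprotein RQ and substrate oxidation rates (lipid, carbohydrate,
    protein); implements the quality control, paired-test, crossover mixed-model
    and metabolite-physiology association analyses used in controlled dietary
    intervention studies; and provides a fully deterministic synthetic cohort
    generator (participants, chamber schedules, gas-exchange traces, metabolite
    panels, NEFA) so the entire pipeline can be exercised without access to
    restricted clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    withr,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
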