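Package: cuprackit
Title: Chemometric Modeling and Validation of Microplate CUPRAC Antioxidant Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the chemometric workup of microplate-based cupric ion
    reducing antioxidant capacity (CUPRAC) measurements: Scheffe quadratic
    mixture modeling and response-surface optimization of ternary solvent
    systems over the simplex, ICH-style calibration validation (linearity by
    lack-of-fit versus pure-error ANOVA, detection and quantification limits,
    back-calculated accuracy, kinetic precision, molar absorptivity), Trolox
    equivalent antioxidant capacity (TEAC) quantification from plate reads,
    and between-sample comparison with Cochran's C, one-way ANOVA and
    multiple-range homogeneous subsets. Includes deterministic synthetic-data
    generators so every stage of the pipeline can be exercised and tested
    without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
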