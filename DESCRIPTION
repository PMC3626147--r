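Package: crctailor
Title: Tailored Colorectal Cancer Screening Messages and Factorial Trial
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Preventive Health Model (PHM), self-efficacy and
    fecal aversion Likert scales used in colorectal cancer screening
    research, assembles stage-tailored feedback messages keyed to the
    Precaution Adoption Process Model (PAPM), and analyses 2x2x2
    (modality x message x time) factorial screening trials: Yates-corrected
    chi-square tests, one-way ANOVA, related-samples t tests and
    mixed between-within ANOVA, together with a calibrated synthetic-cohort
    simulator, participant-flow accounting and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
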