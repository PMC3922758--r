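Package: cmmorph
Title: Quantitative MRI Morphometry for Canine Chiari-Like Malformation and
    Syringomyelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based craniometric analysis of midsagittal MRI of toy-breed
    dogs screened for Chiari-like malformation (CM) and syringomyelia (SM).
    Implements the occipital-lobe circle framework (a minimum enclosing circle
    with its centre constrained to the cranial base line), the derived line and
    angle measurements, BVA/KC-style CM/SM grading and age-conditional cohort
    construction, one-way ANOVA screening, stepwise Wilks-lambda canonical
    discriminant analysis with leave-one-out cross-validation, ROC and
    cutoff-grid diagnostic metrics, and intraclass correlation ICC(2,1)
    reliability, together with seeded synthetic-data generators that emulate
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
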