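Package: snomedcci
Title: SNOMED CT Adaptation of the Charlson Comorbidity Index for Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to adapt International Classification of Diseases (ICD)
    based comorbidity coding algorithms to the SNOMED CT standardized
    vocabulary and to validate the adaptation on claims-shaped data. Builds
    ICD-to-SNOMED codeset crosswalks from OMOP-dialect vocabulary tables with
    auditable back-translation diagnostics (multiple-to-one fan-outs,
    deprecated codes, specificity losses), scores the weighted Charlson
    comorbidity index per patient under either an ICD-based or SNOMED-based
    algorithm, builds inpatient index cohorts with a one-year mortality
    outcome, and compares algorithms via patient-overlap tables, standardized
    mean differences, and the concordance statistic of univariable logistic
    mortality models. Includes a synthetic vocabulary and claims generator so
    the full pipeline runs without licensed vocabularies or data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
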