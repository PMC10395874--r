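Package: fncdr
Title: Clinical Decision Rules for Pediatric Fever in Neutropenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derivation, internal cross-validation and external validation of
    clinical decision rules (CDRs) for pediatric fever in neutropenia (FN).
    Implements integer points risk scores derived from three-level mixed
    logistic regression (random intercepts per patient nested within centers),
    sensitivity-targeted score thresholds, replicated k-fold internal
    cross-validation with in-fold score re-derivation, continuity-corrected
    Wilson confidence intervals for all performance proportions, and a
    registry of eleven published pediatric FN rules with their restricted
    validation dataset filters. A seeded synthetic cohort generator emulates
    the multicenter episode structure (centers, patients, repeated episodes,
    clustered outcome risk) so the whole pipeline is testable without access
    to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
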