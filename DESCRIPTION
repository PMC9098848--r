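Package: dpphqsar
Title: QSAR Classification of Phenolic Antioxidants by Stepwise
    Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for two-group QSAR classification of
    phenolic compounds against DPPH radical scavenging activity: compound
    ingestion from delimited, SDF and SMILES-list formats with a 300 uM
    potency cut point, a pinned 200-descriptor RDKit panel with
    semi-constant filtering, two-sample t-test screening, stepwise
    descriptor selection by the Wilks' lambda criterion, two-group Fisher
    classification functions, and a validation suite (back-substitution,
    jackknife leave-one-out cross-validation, Cohen's kappa, exact
    McNemar test, sensitivity/specificity/Youden index, and a
    standardized descriptor heat map). Ships the published 16-descriptor
    anti-DPPH classifier as a ready-to-run screening endpoint and a
    synthetic-data generator emulating the curated two-class descriptor
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (configurable via option 'dpphqsar.python'), for
    descriptor computation and structure parsing.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
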