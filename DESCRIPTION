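Package: strat4concord
Title: Concordance Analysis for RT-qPCR Breast Cancer Biomarker Calls
    Against IHC and FISH Reference Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the STRAT4 delta-Ct call algorithm for the ESR1, PGR,
    ERBB2 and MKI67 transcripts normalised against the CYFIP1 reference,
    the immunohistochemistry (IHC) and FISH reference-method scoring rules
    for ER, PR, HER2 and Ki67 (hormone-receptor percent cutoffs, H-score,
    HER2 reflex resolution of IHC 2+ equivocals by FISH, Ki67 proliferation
    categories), and the full diagnostic concordance analysis: 2x2 agreement
    tables with exclusion bookkeeping, positive/negative/overall percent
    agreement with Clopper-Pearson or Wilson intervals, Cohen's kappa with
    the Fleiss-Cohen-Everitt asymptotic standard error, ROC curves and AUC
    on delta-Ct scores, and delta-Ct cutoff optimisation by maximal
    concordance. A seeded synthetic cohort generator emulates the joint
    RT-qPCR/IHC/FISH structure of a breast-cancer FFPE specimen collection
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
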