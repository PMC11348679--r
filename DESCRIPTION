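Package: pmdscore
Title: Myelination Scoring and Subtype Stratification for
    Pelizaeus-Merzbacher Disease MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a visual, semiquantitative myelination score for
    Pelizaeus-Merzbacher disease (PMD) built from ordinal grades of
    white-matter structures on conventional T2- and T1-weighted MRI, together
    with the analytics used to develop and apply it: rule-based and
    threshold-based severity classification, linearly weighted multi-rater
    concordance robust to kappa paradoxes with Cicchetti categorisation and
    item selection, PCA unifactoriality checks, ROC analysis with Youden
    cut-offs, pairwise Wilcoxon group comparisons, brain-volume surrogates
    (bicaudate ratio, pons diameter, thin corpus callosum) with age-adapted
    z-scores, and a fully deterministic synthetic cohort generator so the
    entire pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
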