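Package: painmarkers
Title: Longitudinal Within-Subject Discovery and Convergent Evidence Scoring of
    Blood Biomarkers for Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stepwise pipeline for discovering and evaluating blood
    gene-expression biomarkers of pain state and of future emergency-department
    visits for pain. Implements within-subject longitudinal discovery scoring of
    probesets from paired low-pain/high-pain visits (absent/present call
    switching and fold-change concordance, 0-6 internal points), prioritization
    by a convergent functional genomics external evidence score (0-12 points
    over six literature-evidence categories), validation by stratified z-scoring
    and stepwise-change one-way ANOVA against a clinically severe pain cohort
    (0-6 points), independent-cohort testing of state and trait prediction with
    ROC/t-test/Pearson/Cox/odds-ratio metrics in all subjects and in gender and
    gender-by-diagnosis strata, and tabulation of a convergent functional
    evidence score (maximum 48) that ranks biomarkers across all steps. Includes
    a synthetic-cohort generator with planted algogenes, pain-suppressor genes,
    and marker-dependent emergency-visit hazards for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
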