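Package: devscreen
Title: Normative Deviance Scoring and Pairwise Classification of Motor Speech Disorders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening motor speech disorders from a fixed battery of
    speech measures. Builds age- and sex-stratified centile references from a
    neurotypical cohort, converts raw measures into ordinal deviance scores
    (0-4 per measure, composite scores up to 6 for the multi-measure voice and
    diadochokinetic dimensions, and a seven-dimension total), and discriminates
    pairs of clinical groups with depth-limited Gini decision trees validated
    by leave-one-speaker-out cross-validation, including normalized Gini
    feature importances. A seeded simulator generates normative cohorts and
    patient groups with prescribed deviance profiles so the whole pipeline can
    be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
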