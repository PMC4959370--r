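Package: progmod
Title: Prognostic Gene-Expression Module Discovery and Survival Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers paired prognostic gene-expression modules from a
    training cohort and scores patients on new cohorts. Each gene is screened
    genome-wide by a quartile-split log-rank test with hazard-ratio and
    fold-change filters; prognostic genes are clustered into co-expression
    cliques (Pearson correlation graph, iterative exact maximum-clique
    extraction) and anticorrelated high-risk/low-risk cliques are paired by
    maximal bi-clique search into scoring modules. A per-sample score is the
    ratio (or log-scale difference) of the median expression of a module's
    high-risk genes to its low-risk genes; patients are stratified at the
    score median or quartiles and strata are compared by Kaplan-Meier curves
    and the log-rank test. Includes differential-expression screening between
    clinical groups, covariate association summaries, and a synthetic cohort
    generator with planted co-expression blocks and proportional-hazards
    survival for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
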