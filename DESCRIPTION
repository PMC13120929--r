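Package: ptra
Title: Patient Trajectory Analysis for Longitudinal Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines directed disease trajectories from longitudinal clinical
    event data. Converts per-patient visit, relapse, imaging and treatment
    streams into dated diagnostic events, scores every ordered event pair by
    the relative risk of the outcome within a lag window against age- and
    sex-matched resampled controls, derives empirical p-values from repeated
    control resampling, selects the dominant temporal direction with an exact
    binomial test, chains the surviving pairs into a directed trajectory
    graph, partitions it with the Markov Clustering algorithm and reports
    per-cluster demographics with a finite-population Z-test for gender
    proportions. Includes a synthetic longitudinal-cohort generator with
    planted lagged dependencies (known hazard ratios) so that calibration and
    recovery of the whole pipeline can be tested without clinical data.
    Developed around multiple-sclerosis disability scoring (EDSS, functional
    system scores, disease-modifying-therapy switches) but the pair-risk
    machinery is event-type agnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
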