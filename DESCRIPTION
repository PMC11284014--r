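Package: receptivr
Title: Hour-Resolution Endometrial Receptivity Testing and Personalized
    Embryo Transfer Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for RNA-seq-based endometrial receptivity testing (rsERT)
    with hourly precision. Simulates transcriptome cohorts in which marker
    gene expression tracks each patient's window of implantation (WOI),
    constructs signed hour-offset training labels from biopsy sampling times
    and successful transfer times, ranks receptivity marker genes, and fits a
    bagged regression-tree ensemble that predicts the WOI hour offset with
    infinitesimal-jackknife standard errors and patient-grouped
    cross-validation. Single-biopsy predictions are turned into clinical
    receptivity reports (pre-receptive, receptive, post-receptive), converted
    into personalized embryo-transfer schedules that fix the transfer clock
    hour and float the first progesterone injection, and evaluated with 2x2
    contingency statistics: odds ratios with Woolf confidence intervals,
    chi-square tests, and covariate-adjusted odds ratios from an iteratively
    reweighted least-squares logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
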