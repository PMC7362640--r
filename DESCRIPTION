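Package: drgscreen
Title: Two-Step Unsupervised Screening for DRG Upcoding in Hospital Discharge Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening hospital providers for anomalous DRG
    (Diagnosis Related Group) coding behavior from administrative hospital
    discharge charts. Step One clusters providers on behavioral features
    (relative DRG mix, costs, length of stay, specialization, complication
    shares) using k-means with ensemble Principal Feature Analysis and a
    silhouette-maximizing grid search over the number of selected features
    and clusters, then flags providers unusually far from their own cluster
    centroid (95th-percentile local distances). Step Two builds auditor
    decision-support reports: percentile positions of each flagged provider
    on fraud-related indexes, and log-scale comparisons of its patients'
    casemix (age, length of stay, comorbidity, costs) against the
    population. A synthetic-claims generator with known behavior groups and
    planted deviants makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
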