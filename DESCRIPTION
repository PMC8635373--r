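Package: scfc
Title: Structure-Function Connectome Coupling Analysis for Multi-Site Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired structural (fiber-count) and
    functional (Fisher-z correlation) brain connectivity matrices on the
    AAL-90 parcellation. Computes binary global efficiency of thresholded
    structural and functional networks, per-subject structure-function
    (SC-FC) coupling as the Spearman correlation between log fiber counts
    and functional connectivity within canonical subnetworks (default mode,
    executive control, salience), harmonizes subject-level features across
    acquisition sites with parametric empirical-Bayes ComBat, and runs the
    group-level inferential layer: ANCOVA with age and sex covariates,
    Tukey and Welch post-hoc contrasts, edgewise FDR-controlled group
    contrasts, and Fisher r-to-z tests for differences between independent
    correlations. Includes a synthetic-cohort generator producing paired
    SC/FC matrices, two-site batch structure, demographics, and behavioral
    scores with tunable coupling strength, so the full pipeline is testable
    without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    igraph,
    optparse
Config/testthat/edition: 3
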