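Package: tdnet
Title: Temporal Disease Networks from Longitudinal Diagnosis Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds temporal disease networks from longitudinal outpatient
    diagnosis records coded in ICD-9-CM. Converts visit-level records into
    per-patient first-occurrence disease paths, counts directed
    consecutive-transition edges between 3-digit diagnoses, tests each
    directed pair with a one-sided Fisher exact test with
    Benjamini-Hochberg correction, and applies prevalence, pair-count and
    death-code filters to obtain a statistically filtered directed network.
    Provides weighted-degree, PageRank and betweenness centralities, an
    8-year fatality metric, map-equation (Infomap) flow communities scored
    by a normalized chapter-entropy H score, inverted-weight shortest-path
    disease trajectories, and a synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph (>= 1.3),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
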