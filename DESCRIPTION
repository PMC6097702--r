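Package: coactnet
Title: Co-Activation Network Analysis of Regional Immediate-Early-Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds task-evoked functional connectivity networks from
    subject-level regional expression of activity markers (for example
    pCREB-positive nuclei densities), following the correlation-network
    workflow used in lesion studies of contextual fear conditioning.
    Provides Pearson correlation matrices with exact two-tailed p-values,
    p-value thresholded weighted graphs, global and local efficiency with
    degree-preserving rewired null ensembles for small-world assessment,
    quartile-intersection hub identification over four centrality metrics,
    label-permutation tests of group centrality differences, Fisher-Z
    edge-difference z-scores, and bootstrap-resampled behavioral statistics
    (ANOVA, t, Kolmogorov-Smirnov, Cohen's d). A synthetic-data generator
    with plantable hub and community structure makes every stage testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
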