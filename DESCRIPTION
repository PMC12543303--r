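Package: fixelcouple
Title: Fixel-Based Structure-Function Connectome Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-level structure-function coupling analysis for weighted brain
    connectomes built from fixel-based white-matter metrics (fiber density,
    log fiber-bundle cross-section, and their combination) alongside
    conventional streamline counts. Provides connectome containers with
    explicit missing-edge masks, subject-level and group-level coupling
    correlations, edge-wise and node-strength-wise permutation inference with
    Bonferroni and false-discovery-rate control, Fisher r-to-Z comparison of
    group-average couplings, ANCOVA with marginal-means contrasts, a
    one-factor confirmatory factor analysis memory composite, regressions of
    default-mode-network coupling on cognition, and a seeded synthetic-cohort
    generator with planted coupling structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
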