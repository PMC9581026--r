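Package: diffint
Title: Differential Interactome Analysis for Two-Phenotype Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects protein-protein interactions whose joint co-expression
    states differ between two phenotypes (for example normal versus tumor
    tissue), using three-level expression discretization, per-state
    observation frequencies and the q statistic. Builds hub-centred modules
    of differentially interacting proteins, intersects module catalogues
    across independent datasets, scores module prognostic power through Cox
    regression, Kaplan-Meier stratification and log-rank testing, and ranks
    candidate drugs against module members by hypergeometric
    over-representation. A synthetic-data generator with planted
    differential structure supports validation of every stage without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
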