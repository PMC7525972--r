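Package: glvnet
Title: Microbial Interaction Networks from Replicate Time-Series
    Abundance Data via Generalized Lotka-Volterra Ensembles
Version: 0.1.0
Authors@R:
    person("F.", "Mora", email = "fmora.dev@posteo.net", role = c("aut", "cre"))
Description: Infers signed, directed microbial interaction networks from
    replicate time-series abundance tables (mothur shared-style genus count
    tables) by fitting a discrete generalized Lotka-Volterra regression to
    every member of a replicate-assembly ensemble and retaining interactions
    whose sign recurs in more than a consensus fraction of the ensemble.
    Includes a synthetic-community generator with known ground truth,
    abundance/coreness membership classification, alpha-diversity estimators
    with a permutation t-test, centrality-rank aggregation to nominate key
    microbes, focal-taxon interaction reports, cooperation/competition
    stability comparison between groups, and a configuration-driven pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2,
    vegan
Config/testthat/edition: 3
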