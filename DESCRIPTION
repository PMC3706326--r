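Package: activemods
Title: Active Module Detection in Bipartite Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps per-gene differential-expression results onto a bipartite
    reaction-metabolite metabolic network, scores reactions by the mean log2
    fold-change of their associated genes (with median imputation for
    unscored reactions) and penalises metabolites in proportion to their
    connectivity, then searches for coordinately up- or down-regulated
    connected subnetworks ("active modules") by simulated annealing. Module
    significance is assessed against an empirical null of random connected
    node sets of identical composition, with false-discovery-rate control.
    A one-tailed Fisher's exact pathway enrichment analysis is included for
    comparison, together with a fully seeded synthetic-data generator
    (networks with currency-metabolite hubs, planted modules, replicate-level
    expression) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
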