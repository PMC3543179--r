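Package: symcore
Title: Comparative Core-Metabolism Analysis of Symbiotic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of genome-scale metabolic
    networks across bacteria with different symbiotic lifestyles.
    Computes core, pan and variable sets of reactions, compounds and
    level-3 Enzyme Commission (EC) classes; builds currency-filtered
    reaction graphs and searches them for connected representatives of
    shared enzymatic capabilities; quantifies the influence of the
    smallest networks on core size via leave-out scans; simulates the
    decay of shared-reaction sets under random subsampling and fits
    exponential and logistic asymptote models; simulates differential
    random loss of enzymes with Monte-Carlo testing; and detects
    metabolites potentially acquired from the environment (seed sets)
    from strongly connected components of directed compound graphs.
    Includes a synthetic metabolic-network panel generator so that the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
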