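Package: comethnet
Title: Differential Co-Methylation Network Analysis
Version: 0.1.0
Authors@R:
    person("GAW", "Methods", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construct weighted co-methylation networks from kinship-adjusted
    residual methylation values at two time points, detect trait-associated
    probe modules by topological-overlap clustering, and decide which modules
    change topology after treatment using two independent statistics:
    permutation-based module preservation (Z_summary and medianRank) and a
    generalized Hamming distance test against a permutation-normal null.
    Includes a family-structured synthetic study generator, per-probe linear
    mixed model residualization against a kinship matrix, probe screening and
    quality-control filters, hypergeometric gene-set over-representation of
    changed modules, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
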