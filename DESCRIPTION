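Package: uecr
Title: Episode Clustering of Gene Duplications for Unrooted Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for locating multiple gene duplication episodes on a rooted
    binary species tree from collections of gene family trees. Implements
    rooted reconciliation (lca-mapping, duplication, loss and duplication-loss
    costs), the unrooted reconciliation machinery (edge classes, star types,
    D- and DL-plateaus, greedy optimal-edge search), rooted episode clustering
    via valid mappings and interval stabbing, and exact and heuristic solvers
    for unrooted episode clustering in which each gene tree is rooted on an
    edge of its D-plateau. Includes a duplication-loss simulator for species
    and gene trees, curated fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
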