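Package: rgcore
Title: Reduced-Graph Cores for Lead-Optimisation Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and summarises lead-optimisation compound series by
    reduced-graph (RG) representation. Molecules are collapsed into typed
    node-and-edge summary graphs (rings, hydrogen-bond donor/acceptor groups,
    linkers), series are detected as maximum common RG subgraphs ("RG cores")
    via an iterative graph-Tanimoto neighbourhood procedure, every molecule is
    mapped onto the cores it contains with topological distance maps resolving
    ambiguous mappings, and Markush-style SAR tables with per-substructure
    frequencies and pIC50 statistics are produced. Chemistry perception
    (SMILES, SMARTS, ring and aromaticity models) is delegated to RDKit
    through a bundled Python helper script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.9) with RDKit, available as 'python' on the
    PATH (override with the RGCORE_PYTHON environment variable).
Config/testthat/edition: 3
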