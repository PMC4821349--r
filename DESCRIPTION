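Package: metnet
Title: Consensus Metabolic Network Reconstruction and Constraint-Based Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and interrogating expression-informed
    genome-scale metabolic models across related species. Reads models in an
    SBML subset or a flat TSV dialect; calls per-species gene presence from
    homology hit tables and intersects them into a consensus gene set;
    extracts expression-consistent sub-models with GIMME- and iMAT-style
    algorithms; simulates phenotypes by flux balance analysis, linearized
    minimization of metabolic adjustment, single-gene deletion screening and
    robustness scans; designs knockout strains for product overproduction by
    bounded local search; and provides cross-species RNA-seq statistics
    (RPKM, a simplified negative-binomial differential-expression test,
    outgroup divergence calls, correlation-thresholded coexpression
    networks). Includes generators for synthetic study data - toy metabolic
    models with known optima and essentiality, negative-binomial count
    matrices with planted signal, and homology tables with planted
    presence/absence - so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
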