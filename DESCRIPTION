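Package: sqiome
Title: Composite Soil Quality Index and Microbial Community Analysis for
    Saline-Alkaline Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a composite Soil Quality Index (SQI) built from
    min-max membership functions, principal-component factor-loading
    weights, and variance-contribution aggregation, together with the
    microbial-community statistics it is coupled to in revegetation
    field trials on saline-alkaline soil: alpha diversity (Chao1,
    Shannon, Pielou), Bray-Curtis dissimilarity, principal coordinates
    analysis, redundancy analysis, Mantel tests, Spearman
    genus-environment correlation panels, and correlation-threshold
    OTU co-occurrence networks with a topology metric panel. A
    Dirichlet-multinomial scenario simulator generates replicate-level
    soil chemistry and OTU count tables with planted correlation
    structure so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
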