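Package: psoilcycle
Title: Profiling and Multivariate Analysis of Soil Microbial Phosphorus-Cycling Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing shotgun-metagenomic functional profiles of
    soil microbial phosphorus (P) cycling under long-term nutrient inputs.
    Starting from KEGG-orthology (KO) read-count tables, the package profiles
    a curated 40-gene P-transformation catalog (starvation-response
    regulation, inorganic-P solubilization / organic-P mineralization, and
    P uptake and transport), computes treatment shift statistics, runs
    community ordination (Bray-Curtis, NMDS, ANOSIM) and distance-based
    linear modelling, builds Spearman co-occurrence networks thresholded by
    random matrix theory with FDR edge filtering, and fits observed-variable
    path models linking nutrient inputs, soil pH and N:P stoichiometry to
    gene-category abundances. A synthetic-study generator emulating a
    4-site x 3-treatment x 3-replicate field design makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
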