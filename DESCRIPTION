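Package: phylocascade
Title: Phylogenetic Null Models for Community Assembly Along Reservoir
    Cascades
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions microbial community turnover between connected
    habitats into selection, homogenizing dispersal, dispersal limitation
    and drift using abundance-weighted beta mean nearest taxon distance
    (betaMNTD), the beta nearest taxon index (betaNTI) and the
    abundance-based Raup-Crick metric computed with Bray-Curtis
    dissimilarity (RC-bray). Includes OTU-table input/output, rarefaction
    and subcommunity extraction, PERMANOVA and NMDS on betaMNTD distance
    matrices, PCA of standardized environmental variables, and a
    seed-deterministic simulator of phylogenies, phylogenetically
    conserved niche traits and communities assembled under each of the
    four processes along a four-reservoir cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
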