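Package: caatphylo
Title: Community Phylogenetics of Seasonally Dry Tropical Plant Assemblages
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for testing edaphic and climatic structuring
    of plant community phylogenetic pattern in seasonally dry tropical
    formations. Provides even-spacing (BLADJ-style) node dating of supertree
    topologies, MPD/MNTD-based null-model standardized effect sizes (net
    relatedness and nearest taxon indices, NRI/NTI), a fixed-tree
    trait-reshuffle test of phylogenetic signal in Raunkiaer life forms,
    Moran's I spatial correlograms over equal-count distance classes,
    principal coordinates of neighbour matrices (PCNM) spatial eigenvector
    filters, ANCOVA with edaphic covariates, and climate-versus-edaphic
    variance partitioning. Includes generators for synthetic study systems
    (Yule pool phylogenies, conserved discrete and continuous traits,
    community assembly under neutral, filtering and repulsion rules, and
    spatially autocorrelated site covariates) plus the published 13-site
    Caatinga coordinate and diversity tables as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    picante,
    phangorn,
    vegan,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
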