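Package: forestplots
Title: Diversity Partitioning, Community Classification and Carbon Stocks
    for Nested Forest Plot Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing nested vegetation survey designs
    (island x forest type x plot x subplot): taxonomic diversity indices
    and additive hierarchical partitioning of gamma diversity; community
    classification from Hellinger distances with UPGMA clustering,
    cophenetic model selection, silhouette and Mantel cluster diagnostics,
    non-metric multidimensional scaling, PERMANOVA and indicator-species
    (IndVal) permutation statistics; dendrometric structural diversity
    (density, branch-wise basal area, basal-area Shannon indices); and
    carbon-stock accounting in trees (allometric above-ground biomass,
    root-to-shoot below-ground biomass, leaf-type carbon fractions), leaf
    litter and soil (Van Bemmelen conversion). Includes a seeded synthetic
    survey generator emulating a 3-island x 3-forest-type x 10-plot design
    and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
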