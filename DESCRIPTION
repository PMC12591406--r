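Package: podscape
Title: Social Network and Seascape Habitat Analysis for Photo-Identified Cetacean Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to delineate subpopulations of photo-identified cetaceans
    from encounter records and bathymetry. Standardizes sighting records into
    daily encounters, computes simple-ratio association indices under the
    gambit of the group, clusters the association matrix with average linkage
    and selects the partition maximizing weighted Newman modularity, derives
    barrier-aware geospatial covariates (water depth, distance to shore,
    water distance to the 200 m isobath, continental shelf width, survey
    effort grids) from elevation rasters, regresses associations on habitat
    similarity with MRQAP permutation inference, and fits quantile habitat
    envelopes. Includes a seeded two-subpopulation fission-fusion encounter
    simulator so the whole chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    mclust,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
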