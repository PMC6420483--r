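Package: parcfam
Title: Connectivity-Based Parcellation and Connectional Families of Cortical Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parcellates cortical regions of interest by similarity of their
    whole-hemisphere functional-connectivity profiles using affinity
    propagation with a data-driven preference, groups the resulting parcel
    exemplars into connectional families by hierarchical (Ward, city-block)
    clustering of exemplar-to-exemplar connectivity, and summarizes
    large-scale organization with branch-level affinity matrices, peak
    connections, and axis-gradient statistics. Includes desk-scale
    preprocessing (detrending, nuisance regression, geodesic surface
    smoothing, incremental group PCA, dense-connectome construction) and a
    synthetic-data generator with planted parcels, families, couplings and
    gradients whose closed-form expected connectome serves as a test oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
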