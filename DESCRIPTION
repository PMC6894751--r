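Package: vertexGBE
Title: Vertex-Model Simulation and Tracked-Cell Analysis of Drosophila
    Germband Extension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates convergent extension of the Drosophila germband with
    a two-dimensional vertex model in which shrinking junctions collapse
    into higher-order vertices (protorosettes and rosettes) that resolve
    stochastically at prescribed rates, and in which an extrinsic posterior
    pull is applied as a strain calibrated against the probed tissue
    stiffness. Simulated tissues are exported as tracked-cell tables in
    the same schema used for segmented and tracked embryo movies, and the
    package provides the matching quantification suite: per-cell shape
    descriptors from area- and centroid-constrained ellipse fits, the
    decomposition of tissue strain rates into cell-shape and intercalation
    components on focal-cell domains, and neighbour-exchange (T1) detection
    with angular statistics and resolution-phase durations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
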