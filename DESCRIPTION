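Package: cellflows
Title: Multi-Resolution Cluster Flow Graphs for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds directed acyclic cluster-flow (Sankey) graphs from
    multi-resolution single-cell clustering. Clusters detected at a grid of
    resolution parameters become size-ordered nodes; the cells shared between
    clusters at consecutive resolutions become flows. Flows can be painted by
    single-gene mean expression or by a three-gene co-expression percentage
    statistic rendered as RGB, and summarised in a ternary chart; nodes carry
    silhouette and related cluster-evaluation metrics, one-vs-rest marker
    genes, and user-supplied annotations. Stable cell communities are traced
    across resolutions as maximal chains of high-mutual-proportion flows.
    Includes a shared-nearest-neighbour resolution scan, a planted-hierarchy
    synthetic data generator, JSON and standalone HTML export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
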