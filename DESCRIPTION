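Package: commtrace
Title: Tracking and Timeline Visualization of Evolving Network Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processes the output of any evolutionary (snapshot-by-snapshot)
    community detection method. Consecutive snapshot partitions are linked by a
    weighted directed bipartite map whose edge weights are Jaccard coefficients of
    the member node sets; an adaptive min-of-max significance threshold separates
    genuine correspondences from noise, and the seven canonical evolution events
    (birth, death, continuation, merge, split, growth, shrinkage) are classified.
    Per-interval correspondences are chained with full outer joins into a lineage
    query database, which is drawn as a line-based timeline whose track ordering
    can be refined greedily (or exhaustively for small instances) to reduce line
    cross-overs. Includes a planted-event synthetic benchmark generator with exact
    ground truth, bipartite heatmap and per-snapshot network-configuration plots,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
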