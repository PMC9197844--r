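Package: gmcnet
Title: Graph Neural Network Module Clustering for Weighted Gene
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements gmcNet, a graph-neural-network clustering
    algorithm for weighted gene co-expression network analysis (WGCNA).
    Builds signed topological overlap matrices (full, positive-only and
    negative-only channels) from normalized expression, embeds genes with
    a co-expression pattern recognizer (CEPR) message-passing layer,
    and assigns genes to modules with a softmax classifier trained
    against a MinCut-style cut loss plus an orthogonality loss.
    Includes classical baselines (average-linkage hierarchical
    clustering and PAM K-medoids on topological distance, K-means on
    expression), evaluation metrics (graph modularity, module
    eigengenes, differentially-expressed-module signal, hub genes),
    and a synthetic planted-module expression generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
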