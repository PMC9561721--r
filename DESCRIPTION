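Package: sigportrait
Title: Cross-Study Gene Expression Portraits and Signature-Reversal
    Treatment Scoring
Version: 0.1.0
Authors@R:
    person("Portrait", "Maintainers", email = "maintainers@sigportrait.org",
           role = c("aut", "cre"))
Description: Builds consensus "portraits" of disease gene expression by
    rank-stratum aggregation of many differential-expression studies, and
    scores candidate treatments by how strongly their expression signatures
    reverse the disease portrait. Includes directional hypergeometric
    quadrant analysis of top gene lists, congruence and treatment-reversal
    scores, reversed-gene sets and theoretical treatment combinations,
    rank-rank hypergeometric overlap (RRHO) heatmap grids, a synthetic
    multi-study data generator with planted ground truth, and a deterministic
    end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    digest
Config/testthat/edition: 3
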