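Package: wgcnet
Title: Weighted Gene Co-Expression Network Analysis of Clinical Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from expression
    matrices and relates them to clinical traits. Implements transcript-to-gene
    collapsing by highest average expression, top-expression filtering,
    covariate and principal-component confounder screens, unsigned soft-power
    adjacency with scale-free topology fit, topological overlap, average-linkage
    module detection with an adaptive tree cut and eigengene-based module
    merging, module eigengene/trait correlation with covariate residualization
    and Benjamini-Hochberg false discovery rate control, and quantile-threshold
    intramodular connectivity for hub-gene identification. Includes a
    factor-model simulator that plants co-expression modules and module-trait
    effects with sex/race confounding for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
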