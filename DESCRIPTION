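Package: saltnet
Title: Two-State Gene Co-Expression Networks for Stress-Tolerance Gene
    Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds condition-specific (normal versus stress) gene
    co-expression networks from expression matrices, computes per-gene
    centrality surfaces (degree, Watts-Strogatz clustering coefficient,
    weighted degree, and the geometric-mean weighted clustering
    coefficient), selects genes whose network centrality rises under
    stress, and integrates the resulting candidate sets with SNP
    evidence and a QTL genomic interval to produce a prioritized gene
    list.  Includes median-of-ratios count normalization, a synthetic
    two-condition data generator with planted differential hubs for
    validation, and photometric pigment-content utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    DESeq2
Config/testthat/edition: 3
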