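Package: mirstagenet
Title: Stage-Specific miRNA-Gene Co-Expression Networks for Tumor Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step pipeline for building stage-specific micro-RNA to gene
    regulatory co-expression networks across ordered tumor progression phenotypes
    (non-tumor plus stages I-IV), modeled on clear cell renal carcinoma. Per-phenotype
    bipartite mutual-information network inference with rank binning, negative-binomial
    Wald differential expression over contiguous-stage contrasts, and an opposite-sign
    canonical-regulation edge filter, followed by cross-stage set comparison (UpSet-style
    exclusive intersections), cytoband co-location analysis of co-expressed pairs, and
    tracking of persistently differentially expressed miRNAs and their stage-specific
    targets. Includes a negative-binomial synthetic-data generator with planted
    differential expression and planted coupled miRNA-gene pairs so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
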