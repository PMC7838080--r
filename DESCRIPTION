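Package: bahdscope
Title: Acyl-Acceptor Specificity Prediction for BAHD Acyltransferases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Guilt-by-association plus pocket-electrostatics prediction of the
    acyl-acceptor class of BAHD-family acyltransferases. Provides conserved-motif
    (HXXXD/DFGWG) gating of family membership, an all-vs-all pairwise alignment
    layer with Karlin-Altschul E-values, sequence similarity network (SSN)
    construction and clustering, neighbor-joining phylogenies, Kabsch
    superposition and acyl-acceptor pocket charge profiling, and a synthetic
    protein-superfamily generator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
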