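Package: sigweave
Title: Conserved Cell-Type Gene Signatures from Bulk Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives conserved cell-type and tissue-appendage gene signatures
    from bulk transcriptomes by thresholded Pearson co-expression networks and
    Markov clustering, matches clusters across two expression platforms by
    hypergeometric overlap to build a cross-platform signature catalog, and
    interprets condition-versus-control transcriptomes with per-sample
    signature scores, log fold changes, and a rotation gene-set test with a
    direction-concordance significance rule. Ships a synthetic bulk-mixture
    generator (Dirichlet cell-type proportions, two platforms, multiplicative
    noise, array-like saturation) with known marker ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
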