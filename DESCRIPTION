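Package: emrec
Title: Reconstruction of Near-Full-Length 16S rRNA Genes from Sheared
    Amplicon Short-Read Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-guided reconstruction of near-full-length 16S rRNA
    gene consensus sequences and their relative abundances from paired-end
    short reads of sheared amplicon libraries, using an iterative
    expectation-maximization algorithm with probabilistic read attribution.
    Includes preparation of candidate reference databases (length
    filtering, ambiguity resolution, greedy identity clustering), a
    quality-aware ungapped read mapper, a synthetic sheared-amplicon
    library simulator with fragment end-bias and quality-dependent error
    models, a closed-form expected-coverage calculator, and downstream
    community-table procedures (abundance-ordered OTU picking, adjusted
    expected-count tables, in silico V3 excision, rarefaction with count
    clipping, replicate-specificity screens, and end-bias diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    data.table,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
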