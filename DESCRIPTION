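Package: mipscreen
Title: Screening Annotated Proteomes for Candidate MicroProteins and Their
    Targets
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate microProteins (small single-domain
    post-translational regulators) and their putative multidomain targets
    from an annotated proteome. Implements a filter cascade over protein
    existence levels, a size boundary, bitscore-gated homology search,
    InterPro domain architecture and homolog-family size, followed by a
    sigmoid-weighted composite confidence score built from target coverage
    and the dipeptide-based protein instability index. Also provides
    cross-species conservation filtering, microProtein-target co-expression
    testing, and a synthetic-proteome generator with planted ground truth
    so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
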