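Package: lysmod
Title: Domain-Architecture Dissection of Modular Phage Endolysins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects shared homologous segments among phage endolysin
    (peptidoglycan hydrolase) protein sequences by exact Smith-Waterman
    local alignment with Karlin-Altschul significance, groups them into
    domain families by single-linkage clustering under a dual
    E-value/identity threshold, derives per-protein domain architectures
    and an organization taxonomy, and analyses the combinatorial and
    mosaic structure of the proteins via presence/absence splits networks,
    per-domain neighbor-joining phylogenies with bootstrap support, and
    Robinson-Foulds incongruence scans. Includes a synthetic
    modular-proteome generator with ground-truth tables and recovery
    scoring so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    igraph,
    mclust,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
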