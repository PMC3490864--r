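Package: cellulinker
Title: Segmentation and Sequence Analysis of Cellulase Linker Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting multi-domain cellulases (glycoside hydrolase
    family 6 and 7 catalytic domains joined to family 1 or 2 carbohydrate-binding
    modules) into CBM, linker, and catalytic domain by motif-anchored cutting
    rules, and for characterising the intrinsically disordered linkers:
    length statistics and histograms, pooled amino-acid composition,
    11-bin positional residue-density profiles, N-glycosylation sequon
    statistics, pairwise global alignment with Gonnet scoring for
    percent-identity distributions, and neighbor-joining trees for
    outlier-clade detection. Includes a seeded synthetic-sequence generator
    with per-record truth tables so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
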