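Package: orthosub
Title: Evolution-Guided Design of Residue-Replacement Protein Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs protein variants that eliminate a chosen amino-acid type
    (classically cysteine) by mining natural variation across ortholog
    sequences. Every homolog in a user-supplied database is aligned to the
    query with an exact Smith-Waterman local alignment under affine gap
    penalties, homologs are ranked by percent identity, and for each set of
    structurally coupled target positions the closest homolog carrying
    acceptable replacements at all positions simultaneously donates the
    substitutions. Includes derivation of coupled-position clusters from
    atomic coordinates by heavy-atom contact distance, a synthetic
    ortholog-family generator for fully offline testing, per-position
    variation profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
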