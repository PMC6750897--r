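Package: divlimit
Title: Long-Term Divergence Limits of Orthologous Proteins with Conserved Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how conservation of molecular function limits the
    long-term sequence and structural divergence of orthologous proteins.
    Implements closed-form divergence models (exponential decay, decay to an
    identity floor, and gamma-distributed rate variation), their
    finite-alphabet equivalence with back substitutions, nonlinear
    least-squares fitting with nested-model F-tests and Wald tests of the
    divergence floor, global pairwise alignment with affine gaps and a
    random-alignment identity baseline, edge-disjoint phylogenetically
    independent pair selection, per-site conservation and fitness- or
    structure-stratified divergence curves, growth-rate estimation from
    pooled turbidostat competition read counts, Kabsch superposition RMSD
    summaries, and synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    stringr,
    readr,
    ggplot2,
    ape,
    Biostrings,
    Rcpp,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    bio3d,
    jsonlite
Config/testthat/edition: 3
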