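Package: anchorext
Title: Anchor-Extension Design of Macrocyclic Peptide Binders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for designing head-to-tail cyclic peptide
    binders by anchor extension: starting from a fixed pocket-bound anchor
    residue (a zinc-coordinating thiol amino acid), peptides are grown,
    closed by kinematic loop closure, sequence-designed by simulated
    annealing Monte Carlo with D- and non-canonical amino acids, and
    ranked by surrogate interface metrics (shape complementarity, binding
    energy gap, contacts, buried unsatisfied polar atoms). Includes
    conformational-landscape (funnel) analysis of designed macrocycles
    and four-parameter logistic IC50 fitting of dose-response data, plus
    synthetic toy receptors and fixtures so the whole pipeline runs
    without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
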