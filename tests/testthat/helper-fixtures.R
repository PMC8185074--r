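## Shared fixtures, built in code and cached for the test session.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

toy_complex <- function() {
  fixture("toy_complex", function() {
    toy <- make_toy_receptor(toy_receptor_spec(seed = 2))
    list(receptor = toy$pose, manifest = toy$manifest,
         complex = seed_anchor_in_pocket(toy$pose))
  })
}

## two slabs of alanine pseudo-residues: `nested` gives near-ideal
## complementary surfaces (bumps in grooves), `shifted` a poor fit
slab_pair <- function(kind = c("nested", "rough"), ext = 3.2) {
  kind <- match.arg(kind)
  mk <- function(z, flip, chain, off, jitter = 0, seed = 1) {
    set.seed(seed)
    res <- list()
    for (x in seq(-ext, ext, by = 1.6)) for (y in seq(-ext, ext, by = 1.6)) {
      dz <- if (jitter > 0) runif(1, -jitter, jitter) else 0
      res[[length(res) + 1]] <- place_pseudo_residue(
        "ALA", c(x + off, y + off, z + dz),
        c(0, 0, if (flip) -1 else 1), align = c(1, 0, 0))
    }
    new_pose(res, chain = chain)
  }
  if (kind == "nested") {
    a <- mk(0, TRUE, "A", 0)
    b <- mk(-6.5, FALSE, "B", 0.8)
  } else {
    a <- mk(0, TRUE, "A", 0, jitter = 1.2, seed = 7)
    b <- mk(-6.6, FALSE, "B", 0.2, jitter = 1.2, seed = 8)
  }
  pose_merge(a, b)
}

## a tiny two-chain complex for exact-oracle comparisons (< 200 atoms)
mini_complex <- function() {
  fixture("mini_complex", function() {
    rec <- build_peptide(c("ALA", "SER", "LEU"), c(-60, -45, 180),
                         chain = "A")
    pep <- build_peptide(c("GLY", "ASN"), c(-60, -45, 180), chain = "P")
    ## bring the peptide alongside the receptor
    for (i in seq_along(pep$residues))
      pep$residues[[i]]$atoms <- sweep(pep$residues[[i]]$atoms, 2,
                                       c(0, 5.0, 1.0), `+`)
    pose_merge(rec, pep)
  })
}
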