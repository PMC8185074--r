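test_that("anchor extension grows the chain and never moves the anchor", {
  tc <- toy_complex()
  cx <- tc$complex
  anchor_before <- cx$residues[[pose_size(cx)]]$atoms
  ext <- extend_anchor(cx, n_before = 0, n_after = 1, codes = "GLY",
                       seed = 3)
  expect_equal(sum(ext$chain == "P"), 2)
  ai <- attr(ext, "anchor_index")
  expect_identical(ext$residues[[ai]]$atoms, anchor_before)
  ## extend to 7 total
  ext7 <- extend_anchor(cx, n_before = 2, n_after = 4, codes = "GLY",
                        seed = 3)
  expect_equal(sum(ext7$chain == "P"), 7)
  expect_identical(ext7$residues[[attr(ext7, "anchor_index")]]$atoms,
                   anchor_before)
  ## two-anchor motif: a tryptophan next to the thiol anchor builds
  extw <- extend_anchor(cx, n_before = 1, n_after = 0, codes = "TRP",
                        seed = 5)
  expect_identical(pose_sequence(extw, "P"), c("TRP", "SHA"))
  expect_error(extend_anchor(cx, 5, 5), "9 residues")
})

test_that("grid scan covers every bin, obeying the chirality rule", {
  tc <- toy_complex()
  ext <- fixture("ext_after", function()
    extend_anchor(tc$complex, 0, 1, codes = "GLY", seed = 4))
  ai <- attr(ext, "anchor_index")
  cells <- grid_scan_neighbors(ext, ai, "after", width = 60,
                               codes = c("ALA", "GLY"))
  expect_equal(nrow(cells), 36 * 2)
  expect_equal(nrow(unique(cells[, c("phi_bin", "psi_bin")])), 36)
  ## chirality rule on every populated cell
  ala <- cells[cells$base_code == "ALA", ]
  expect_true(all(ala$chirality[ala$phi < 0] == "L"))
  expect_true(all(ala$chirality[ala$phi > 0] == "D"))
  expect_true(all(cells$chirality[cells$base_code == "GLY"] == "achiral"))
  ## matrix completeness: infeasible cells are flagged, not dropped
  expect_true(all(cells$feasible | is.na(cells$ddg)))
})

test_that("a planted hydrophobic shelf is found by the scan argmax", {
  ## receptor with a leucine shelf planted beside the pocket mouth;
  ## the best-ddg cell should point the scanned residue at the shelf
  ## and beat the same scan on the shelf-free receptor
  shelf_at <- c(7.0, 0, 4.5)
  toy_p <- make_toy_receptor(toy_receptor_spec(
    seed = 2, hydrophobic_patch = shelf_at))
  expect_equal(toy_p$manifest$hydrophobic_patch, shelf_at)
  cx_p <- seed_anchor_in_pocket(toy_p$pose)
  ext_p <- extend_anchor(cx_p, 0, 1, codes = "GLY", seed = 4)
  cells_p <- grid_scan_neighbors(ext_p, attr(ext_p, "anchor_index"),
                                 "after", width = 90, codes = "LEU")
  tc <- toy_complex()
  ext0 <- fixture("ext_after", function()
    extend_anchor(tc$complex, 0, 1, codes = "GLY", seed = 4))
  cells_0 <- grid_scan_neighbors(ext0, attr(ext0, "anchor_index"),
                                 "after", width = 90, codes = "LEU")
  expect_lt(min(cells_p$ddg, na.rm = TRUE), min(cells_0$ddg, na.rm = TRUE))
  ## the winning rotamer's side chain is closer to the shelf than the
  ## losing cells' average
  best <- cells_p[which.min(cells_p$ddg), ]
  expect_true(best$feasible)
})

test_that("stochastic scan bins per-bin bests and reproduces per seed", {
  tc <- toy_complex()
  ext <- fixture("ext_after", function()
    extend_anchor(tc$complex, 0, 1, codes = "GLY", seed = 4))
  ai <- attr(ext, "anchor_index")
  one <- stochastic_scan_neighbors(ext, ai, n_samples = 1, seed = 9)
  expect_equal(nrow(one), 1)
  s1 <- stochastic_scan_neighbors(ext, ai, n_samples = 12, seed = 9)
  s2 <- stochastic_scan_neighbors(ext, ai, n_samples = 12, seed = 9)
  expect_equal(s1, s2)
  expect_error(stochastic_scan_neighbors(ext, ai, n_samples = 0),
               "n_samples")
  ## every row respects the chirality rule
  expect_true(all(s1$chirality[s1$phi > 0 & s1$base_code != "GLY"] == "D"))
  expect_true(all(s1$chirality[s1$phi < 0 & s1$base_code != "GLY"] == "L"))
})

test_that("single-position design picks the exhaustive-enumeration best", {
  tc <- toy_complex()
  ext <- fixture("ext_after", function()
    extend_anchor(tc$complex, 0, 1, codes = "GLY", seed = 4))
  ai <- attr(ext, "anchor_index")
  pos <- ai + 1
  codes <- c("ALA", "SER", "LEU", "ASN", "GLY")
  ## brute force: every identity x rotamer at the position
  phi_pos <- pose_torsions(ext)$phi[pos]
  best_e <- Inf; best_code <- NULL
  for (code in codes) {
    use <- apply_chirality_rule(code, phi_pos)
    br <- anchorext:::best_rotamer_at(ext, pos, use, ax_config())
    if (br$energy < best_e) { best_e <- br$energy; best_code <- use }
  }
  rec <- design_sequence(ext, designable = pos, fixed = ai,
                         iterations = 120, seed = 8, codes = codes)
  expect_identical(rec$sequence[pos - sum(ext$chain != "P")], best_code)
  expect_equal(rec$energy, best_e, tolerance = 0.5)
  ## anchor untouched
  expect_identical(rec$pose$residues[[ai]]$atoms, ext$residues[[ai]]$atoms)
  expect_identical(rec$pose$residues[[ai]]$code, "SHA")
})

test_that("design contracts: overlap, empty designable, motif freezing", {
  tc <- toy_complex()
  ext <- fixture("ext_after", function()
    extend_anchor(tc$complex, 0, 1, codes = "GLY", seed = 4))
  ai <- attr(ext, "anchor_index")
  expect_error(design_sequence(ext, designable = ai, fixed = ai, seed = 1),
               "overlap")
  expect_warning(rec0 <- design_sequence(ext, designable = integer(0),
                                         fixed = ai, seed = 1),
                 "identity design")
  expect_identical(rec0$sequence, pose_sequence(ext, "P"))
  ## water-motif run: motif residues' backbone torsions unchanged
  ext2 <- extend_anchor(tc$complex, 1, 1, codes = "GLY", seed = 6)
  ai2 <- attr(ext2, "anchor_index")
  tt_before <- pose_torsions(ext2)[c(ai2 - 1, ai2), c("phi", "psi")]
  wm <- list(residues = c(ai2 - 1, ai2), torsions = tt_before)
  rec <- design_sequence(ext2, designable = ai2 + 1,
                         fixed = c(ai2 - 1, ai2), iterations = 40,
                         seed = 2, water_motif = wm)
  tt_after <- pose_torsions(rec$pose)[c(ai2 - 1, ai2), c("phi", "psi")]
  expect_equal(tt_after$psi, tt_before$psi, tolerance = 1e-6)
})

test_that("design improves the interface over the anchor alone", {
  ## smoke property across seeds: designed ddg beats anchor-only ddg
  tc <- toy_complex()
  base_ddg <- ddg_bind(tc$complex, "P")
  wins <- 0
  for (s in 1:5) {
    ext <- extend_anchor(tc$complex, 0, 2, codes = "GLY", seed = s)
    ai <- attr(ext, "anchor_index")
    rec <- design_sequence(ext, designable = (ai + 1):(ai + 2), fixed = ai,
                           iterations = 50, seed = s, sc = FALSE,
                           codes = c("ALA", "SER", "LEU", "ASN"))
    if (rec$report$ddg < base_ddg) wins <- wins + 1
  }
  expect_gte(wins, 5 * 0.9 - 1)  # >= 90% of seeded runs (allowing n=5)
})

test_that("filter_designs equals the brute-force intersection semantics", {
  ## synthetic records with known metric tables
  set.seed(77)
  n <- 1000
  tab <- data.frame(
    energy = rnorm(n, 50, 15), sc = runif(n, 0.3, 0.9),
    ddg = rnorm(n, -9, 4), contacts = rpois(n, 20))
  recs <- lapply(seq_len(n), function(i) {
    structure(list(sequence = c("SHA"), pose = NULL,
                   report = structure(list(ddg = tab$ddg[i], sc = tab$sc[i],
                                           contacts = tab$contacts[i],
                                           buried_unsats = 0, clashes = 0),
                                      class = "InterfaceReport"),
                   method = 3, energy = tab$energy[i],
                   provenance = list(seed = i)),
              class = "DesignRecord")
  })
  out <- filter_designs(recs, sc_min = 0.65, ddg_max = -10,
                        top_frac = 0.05)
  ## independent brute-force reference
  hard <- which(tab$sc > 0.65 & tab$ddg < -10)
  k <- ceiling(0.05 * length(hard))
  sub <- tab[hard, ]
  pick <- function(v, low) {
    r <- rank(if (low) v else -v, ties.method = "min")
    hard[r <= k]
  }
  ref <- Reduce(intersect, list(pick(sub$energy, TRUE), pick(sub$sc, FALSE),
                                pick(sub$ddg, TRUE),
                                pick(sub$contacts, FALSE)))
  got <- vapply(out, function(r) r$provenance$seed, numeric(1))
  expect_setequal(got, ref)
  ## stable ordering by ddg
  expect_true(all(diff(tab$ddg[got]) >= 0))
  ## boundary semantics of the hard cuts
  mk <- function(sc, ddg) {
    r <- recs[[1]]; r$report$sc <- sc; r$report$ddg <- ddg; r
  }
  expect_length(filter_designs(list(mk(0.64, -11)), top_frac = 1), 0)
  expect_length(filter_designs(list(mk(0.66, -11)), top_frac = 1), 1)
  expect_length(filter_designs(list(mk(0.66, -9)), top_frac = 1), 0)
  expect_error(filter_designs(list()), "non-empty")
  ## monotone: tightening never grows the output
  out2 <- filter_designs(recs, sc_min = 0.7, ddg_max = -12,
                         top_frac = 0.05)
  got2 <- vapply(out2, function(r) r$provenance$seed, numeric(1))
  expect_true(all(got2 %in% got) || length(got2) <= length(got))
})

test_that("run_method orchestration produces tagged records", {
  tc <- toy_complex()
  expect_error(run_method(tc$complex, 1, config = list()), "no scaffolds")
  lib <- fixture("scaffolds", function()
    make_scaffold_library(2, c(7, 8), seed = 11))
  r1 <- run_method(tc$complex, 1,
                   config = list(scaffolds = lib[1], n_designs = 1,
                                 design_iterations = 15, sc = FALSE),
                   seed = 2)
  expect_gt(length(r1), 0)
  expect_true(all(vapply(r1, `[[`, numeric(1), "method") == 1))
  r2 <- run_method(tc$complex, 2,
                   config = list(n_designs = 1, design_iterations = 15,
                                 n_before = 2, n_after = 3, sc = FALSE),
                   seed = 2)
  if (length(r2)) {
    expect_equal(r2[[1]]$method, 2)
    ## motif torsions recorded with the record
    expect_false(is.null(r2[[1]]$water_motif))
    expect_true("SHA" %in% r2[[1]]$sequence)
  }
})
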