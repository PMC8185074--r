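test_that("energy terms behave at their construction points", {
  cfg <- ax_config()
  ## zinc restraint vanishes exactly at the target distance
  tc <- toy_complex()
  e <- total_energy(tc$complex, cfg)
  br <- attr(e, "breakdown")
  expect_equal(unname(br["zn"]), 0, tolerance = 1e-9)
  expect_true(all(is.finite(br)))
  ## achiral terms: mirror image of a lone peptide scores identically
  tor <- rbind(c(-60, -45, 180), c(-70, 130, 180), c(-60, -40, 180))
  a <- build_peptide(c("ALA", "SER", "LEU"), tor)
  b <- build_peptide(c("DAL", "DSN", "DLE"), -tor)
  expect_equal(as.numeric(total_energy(a, cfg)),
               as.numeric(total_energy(b, cfg)), tolerance = 1e-6)
  ## determinism
  expect_identical(as.numeric(total_energy(a, cfg)),
                   as.numeric(total_energy(a, cfg)))
})

test_that("split Lennard-Jones has zero repulsion at vdW contact", {
  ## two isolated carbon-like atoms probed through the compiled kernel
  probe <- function(d) {
    anchorext:::pair_energy_cpp(
      rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.7), c(0, 0),
      c(0L, 0L), matrix(integer(0), 2, 0), c(TRUE, TRUE))
  }
  at_contact <- probe(3.4)
  expect_equal(at_contact[["lj_rep"]], 0, tolerance = 1e-12)
  expect_equal(at_contact[["lj_atr"]], -0.15, tolerance = 1e-12)
  ## attractive branch is minimal exactly at contact
  expect_gt(probe(3.8)[["lj_atr"]], at_contact[["lj_atr"]])
  expect_gt(probe(2.8)[["lj_rep"]], 0)
})

test_that("ddg_bind vanishes at long range and matches the oracle", {
  cfg <- ax_config()
  cx <- mini_complex()
  expect_equal(ddg_bind(cx, "P", cfg = cfg), oracle_ddg(cx, "P", cfg),
               tolerance = 1e-6)
  ## translate the peptide 100 A away: no interaction
  far <- cx
  for (i in which(far$chain == "P"))
    far$residues[[i]]$atoms <- sweep(far$residues[[i]]$atoms, 2,
                                     c(100, 0, 0), `+`)
  expect_equal(ddg_bind(far, "P", cfg = cfg), 0, tolerance = 1e-6)
  expect_error(ddg_bind(cx, "Q"), "no chain")
  ## the toy pocket complex also matches the double-loop oracle
  tc <- toy_complex()
  expect_equal(ddg_bind(tc$complex, "P", cfg = cfg),
               oracle_ddg(tc$complex, "P", cfg), tolerance = 1e-6)
})

test_that("contact counting is exact at the boundary and vs the oracle", {
  cx <- mini_complex()
  expect_equal(count_contacts(cx, "P", "A"),
               oracle_contacts(cx, "P", "A"))
  ## boundary: two single-atom chains straddling the cutoff
  mk <- function(d) {
    a <- build_peptide("GLY", c(-60, -45, 180), chain = "A")
    b <- build_peptide("GLY", c(-60, -45, 180), chain = "B")
    a$residues[[1]]$atoms <- a$residues[[1]]$atoms["CA", , drop = FALSE]
    b$residues[[1]]$atoms <- b$residues[[1]]$atoms["CA", , drop = FALSE]
    b$residues[[1]]$atoms[1, ] <- a$residues[[1]]$atoms[1, ] + c(d, 0, 0)
    pose_merge(a, b)
  }
  expect_equal(count_contacts(mk(4.49), "A", "B"), 1)
  expect_equal(count_contacts(mk(4.51), "A", "B"), 0)
  ## separated chains: none
  expect_equal(count_contacts(mk(100), "A", "B"), 0)
})

test_that("clash counting matches the brute-force oracle", {
  p <- build_peptide(c("ALA", "GLY"), c(-60, -45, 180))
  expect_equal(clash_count(p), 0)
  expect_equal(clash_count(p), oracle_clashes(p))
  ## plant k extra overlapping waters far from the chain: each pair of
  ## (water, planted neighbor water) overlaps once
  k <- 3
  w <- do.call(rbind, lapply(seq_len(k), function(i)
    rbind(c(50 + 10 * i, 0, 0), c(50 + 10 * i + 2.0, 0, 0))))
  p$waters <- list(positions = w, structural = rep(TRUE, nrow(w)))
  expect_equal(clash_count(p), k)
  expect_equal(clash_count(p), oracle_clashes(p))
  ## two carbons at 2.0 A (via a distorted chi) register as clashing
  q <- build_peptide(c("LEU", "GLY"), c(-60, -45, 180))
  expect_equal(clash_count(q), oracle_clashes(q))
})

test_that("buried unsatisfied polar atoms need burial and lack of partner", {
  ## a lone exposed dipeptide: every polar atom is solvent-exposed
  p <- build_peptide(c("ALA", "ALA"), c(-60, -45, 180))
  expect_equal(buried_unsats(p), 0L)
  ## bury a lone water deep in a pure-carbon cage (polar backbone
  ## atoms stripped so no hydrogen-bond partner exists)
  cage <- function(center, with_water_at = NULL) {
    pts <- as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3),
                                 z = c(-3, 0, 3)))
    pts <- pts[rowSums(abs(pts)) > 0, ]
    res <- lapply(seq_len(nrow(pts)), function(i) {
      r <- place_pseudo_residue("ALA", center + pts[i, ] * 1.4, c(0, 0, 1))
      r$atoms <- r$atoms[c("CA", "CB", "C"), , drop = FALSE]
      r
    })
    w <- rbind(center,
               if (!is.null(with_water_at)) with_water_at)
    pose <- new_pose(res, chain = "A")
    pose$waters <- list(positions = w, structural = rep(TRUE, nrow(w)))
    pose
  }
  lone <- cage(c(0, 0, 0))
  paired <- cage(c(0, 0, 0), with_water_at = c(2.8, 0, 0))
  expect_gte(buried_unsats(lone), 1L)
  expect_lt(buried_unsats(paired), buried_unsats(lone))
})

test_that("shape complementarity separates nested from rough surfaces", {
  nested <- slab_pair("nested")
  rough <- slab_pair("rough")
  sc_n <- shape_complementarity(nested, "A", "B")
  sc_r <- shape_complementarity(rough, "A", "B")
  expect_gt(sc_n, 0.75)
  expect_lt(sc_r, 0.5)
  expect_gt(sc_n, sc_r + 0.2)
  ## symmetric in chain order
  expect_equal(shape_complementarity(nested, "B", "A"), sc_n,
               tolerance = 1e-9)
  ## invariant under rigid motion of the whole complex
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  moved <- nested
  for (i in seq_along(moved$residues))
    moved$residues[[i]]$atoms <-
      sweep(moved$residues[[i]]$atoms %*% t(R), 2, c(5, -3, 2), `+`)
  expect_equal(shape_complementarity(moved, "A", "B"), sc_n,
               tolerance = 0.02)
  ## out-of-range chains refuse to report
  apart <- nested
  for (i in which(apart$chain == "B"))
    apart$residues[[i]]$atoms <- sweep(apart$residues[[i]]$atoms, 2,
                                       c(0, 0, -100), `+`)
  expect_error(shape_complementarity(apart, "A", "B"), "no interface")
})

test_that("minimization descends and respects restraints", {
  cfg <- ax_config()
  tc <- toy_complex()
  cx <- tc$complex
  ## perturb the anchor's chi angles away from the seeded pose
  pert <- set_torsion(cx, pose_size(cx), "chi2", -100)
  e0 <- as.numeric(total_energy(pert, cfg))
  out <- minimize_pose(pert, "P", max_iter = 25, cfg = cfg,
                       free = "chi")
  expect_lte(attr(out, "energy_final"), attr(out, "energy_initial"))
  expect_lte(as.numeric(total_energy(out, cfg)), e0 + 1e-6)
  ## the anchor's first-residue backbone is bitwise preserved
  expect_identical(out$residues[[pose_size(out)]]$atoms[c("N", "CA", "C"), ],
                   pert$residues[[pose_size(pert)]]$atoms[c("N", "CA", "C"), ])
  ## restrained minimization stays near the start
  pep <- build_peptide(c("ALA", "SER", "LEU", "ALA"), c(-60, -45, 180))
  start <- coords_matrix(pose_atoms(pep, FALSE))
  rel <- minimize_pose(pep, restrain_to_start = TRUE, w_cst = 50,
                       max_iter = 30, cfg = cfg)
  moved <- coords_matrix(pose_atoms(rel, FALSE))
  expect_lt(sqrt(mean(rowSums((moved - start)^2))), 1.0)
})
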