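test_that("closure solutions satisfy ideal ring geometry", {
  base <- build_peptide(rep("GLY", 7), c(-60, -45, 180))
  sols <- close_macrocycle(closure_problem(base, fixed_residues = 1L,
                                           attempts = 120), seed = 7)
  expect_gt(length(sols), 0)
  cfg <- ax_config()
  for (s in sols) {
    expect_lt(abs(s$closure_bond_length - cfg$ideal_cn),
              cfg$closure_tol_len)
    expect_lt(abs(s$closure_bond_angles[1] -
                  anchorext:::BACKBONE_GEOM$a_ca_c_n), cfg$closure_tol_ang)
    expect_lt(abs(s$closure_bond_angles[2] -
                  anchorext:::BACKBONE_GEOM$a_c_n_ca), cfg$closure_tol_ang)
    expect_lte(s$residual, 1e-6)
    expect_gte(s$internal_hbonds, cfg$min_genkic_hbonds)
    expect_true(s$rama_ok)
    expect_true(closure_valid(s$pose, cfg))
    ## anchor coordinates preserved bitwise
    expect_identical(s$pose$residues[[1]]$atoms, base$residues[[1]]$atoms)
  }
})

test_that("re-applying a solution's torsions reproduces its coordinates", {
  base <- build_peptide(rep("GLY", 7), c(-60, -45, 180))
  sols <- close_macrocycle(closure_problem(base, fixed_residues = 1L,
                                           attempts = 150), seed = 3,
                           n_solutions = 1)
  s <- sols[[1]]
  tt <- s$torsions
  rebuilt <- build_peptide(pose_sequence(s$pose),
                           cbind(ifelse(is.na(tt$phi), -60, tt$phi),
                                 tt$psi, tt$omega), cyclic = TRUE)
  ## same internal geometry: superposes exactly
  a <- coords_matrix(pose_atoms(rebuilt, FALSE))
  b <- coords_matrix(pose_atoms(s$pose, FALSE))
  expect_lt(superpose(a, b)$rmsd, 1e-5)
})

test_that("closure is deterministic per seed", {
  base <- build_peptide(rep("GLY", 7), c(-60, -45, 180))
  s1 <- close_macrocycle(closure_problem(base, attempts = 60), seed = 11)
  s2 <- close_macrocycle(closure_problem(base, attempts = 60), seed = 11)
  expect_equal(length(s1), length(s2))
  if (length(s1))
    expect_equal(s1[[1]]$pose$residues, s2[[1]]$pose$residues,
                 tolerance = 1e-12)
})

test_that("geometrically infeasible problems return an empty diagnosis", {
  ## 3-mer with two fixed residues 12 A apart can never close
  tri <- build_peptide(c("GLY", "GLY", "GLY"), c(-60, -45, 180))
  tri$residues[[3]]$atoms <- sweep(tri$residues[[3]]$atoms, 2,
                                   c(12, 0, 0), `+`)
  out <- close_macrocycle(closure_problem(tri, fixed_residues = c(1L, 3L),
                                          attempts = 20), seed = 1)
  expect_length(out, 0)
  expect_match(attr(out, "diagnosis"), "infeasible")
})

test_that("solver beats a fine brute-force torsion grid on a 5-mer", {
  base <- build_peptide(rep("GLY", 5), c(-60, -45, 180))
  ## a 5-ring needs strained torsions: relax the sampling filters so
  ## the test exercises the solver, not the filter
  sols <- close_macrocycle(closure_problem(base, fixed_residues = 1L,
                                           attempts = 300), seed = 5,
                           cfg = ax_config(min_genkic_hbonds = 0,
                                           rama_cutoff = 20),
                           n_solutions = 1)
  expect_gt(length(sols), 0)
  s <- sols[[1]]
  expect_lte(s$residual, 1e-6)
  ## residual landscape around the solution, probed over two of the
  ## solved torsions on nested grids: no grid point beats the solver
  tt <- s$torsions
  n <- 5
  resid_at <- function(dphi, dpsi) {
    p <- s$pose
    p2 <- set_torsion(p, 3, "phi", wrap_angle(tt$phi[3] + dphi))
    p2 <- set_torsion(p2, 3, "psi", wrap_angle(tt$psi[3] + dpsi))
    g <- closure_geometry(p2)
    abs(g$length - ax_config()$ideal_cn)
  }
  best_grid <- Inf
  for (step in c(5, 0.5, 0.05)) {
    for (dphi in step * (-2:2)) for (dpsi in step * (-2:2)) {
      if (dphi == 0 && dpsi == 0) next
      best_grid <- min(best_grid, resid_at(dphi, dpsi))
    }
  }
  solver_resid <- abs(s$closure_bond_length - ax_config()$ideal_cn)
  expect_lte(solver_resid, best_grid + 1e-12)
  expect_lte(solver_resid, 1e-6 + ax_config()$closure_tol_len)
})

test_that("closing a mirrored sequence with mirrored seeds gives mirror rings", {
  cfg <- ax_config(min_genkic_hbonds = 0)
  base_l <- build_peptide(c("ALA", rep("GLY", 6)), c(-60, -45, 180))
  base_d <- build_peptide(c("DAL", rep("GLY", 6)), c(60, 45, 180))
  sl <- close_macrocycle(closure_problem(base_l, attempts = 150), seed = 2,
                         cfg = cfg, n_solutions = 3)
  sd <- close_macrocycle(closure_problem(base_d, attempts = 150), seed = 2,
                         cfg = cfg, n_solutions = 3)
  expect_gt(length(sl), 0)
  expect_gt(length(sd), 0)
  ## each L solution has a mirror-image counterpart obtainable by
  ## rebuilding with negated torsions
  s <- sl[[1]]
  tt <- s$torsions
  mir <- build_peptide(vapply(pose_sequence(s$pose), mirror_code,
                              character(1)),
                       cbind(-ifelse(is.na(tt$phi), -60, tt$phi),
                             -tt$psi, tt$omega), cyclic = TRUE)
  expect_true(closure_valid(mir, ax_config()))
})

test_that("ensemble sampling honors filters and reproduces per seed", {
  cfg <- ax_config()
  ens <- sample_closed_ensemble(rep("GLY", 7), 10, seed = 21)
  expect_gte(length(ens), 8)
  for (p in ens) {
    expect_true(closure_valid(p, cfg))
    expect_gte(internal_backbone_hbonds(p), cfg$min_final_hbonds)
  }
  ens2 <- sample_closed_ensemble(rep("GLY", 7), 10, seed = 21)
  expect_equal(lapply(ens, `[[`, "residues"),
               lapply(ens2, `[[`, "residues"), tolerance = 1e-12)
  ## a stricter hydrogen-bond filter is honored
  ens3 <- sample_closed_ensemble(rep("GLY", 7), 5, seed = 4,
                                 cfg = ax_config(min_final_hbonds = 3))
  for (p in ens3) expect_gte(internal_backbone_hbonds(p), 3)
})
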