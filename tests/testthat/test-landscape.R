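test_that("pnear matches its closed forms and the direct-sum oracle", {
  ## all points at the design -> pnear = 1
  all0 <- data.frame(energy = c(1, 2, 3), rmsd = c(0, 0, 0))
  expect_equal(funnel_stats(all0)$pnear, 1)
  ## equal energies, half at rmsd 0, half far beyond lambda -> 0.5
  half <- data.frame(energy = rep(5, 10), rmsd = rep(c(0, 50), each = 5))
  expect_equal(funnel_stats(half)$pnear, 0.5, tolerance = 1e-12)
  ## planted two-basin landscape vs the direct weighted sum
  set.seed(19)
  basin <- data.frame(
    energy = c(rnorm(12, 2, 0.5), rnorm(8, 5, 0.5)),
    rmsd = c(abs(rnorm(12, 0.5, 0.2)), abs(rnorm(8, 4, 0.4))))
  fs <- funnel_stats(basin, lambda = 1.5, kT = 1)
  expect_equal(fs$pnear, oracle_pnear(basin$energy, basin$rmsd, 1.5, 1),
               tolerance = 1e-12)
  expect_true(fs$pnear >= 0 && fs$pnear <= 1)
  ## energy gap sign reflects where the minimum lives
  expect_gt(fs$energy_gap, 0)
  expect_error(funnel_stats(basin[1, , drop = FALSE]), "at least 2")
})

test_that("pnear never increases when adding a low-energy far point", {
  set.seed(4)
  base <- data.frame(energy = rnorm(20, 3), rmsd = abs(rnorm(20, 1, 0.5)))
  p0 <- funnel_stats(base)$pnear
  for (e_far in c(2, 0, -2)) {
    worse <- rbind(base, data.frame(energy = e_far, rmsd = 8))
    expect_lte(funnel_stats(worse)$pnear, p0 + 1e-12)
  }
})

test_that("cyclic RMSD is register-invariant and zero on renumbering", {
  ens <- fixture("gly_ens", function()
    sample_closed_ensemble(rep("GLY", 7), 4, seed = 13))
  a <- ens[[1]]
  ## renumber the ring start: same structure, rmsd ~ 0
  for (shift in c(1, 3)) {
    b <- a
    ord <- ((seq_len(7) - 1 + shift) %% 7) + 1
    b$residues <- b$residues[ord]
    expect_lt(cyclic_rmsd(b, a), 1e-9)
  }
  ## symmetric
  expect_equal(cyclic_rmsd(ens[[1]], ens[[2]]),
               cyclic_rmsd(ens[[2]], ens[[1]]), tolerance = 1e-9)
  expect_error(cyclic_rmsd(a, build_peptide(rep("GLY", 5))), "length")
})

test_that("landscapes include the design point on request and reproduce", {
  ens <- fixture("gly_ens", function()
    sample_closed_ensemble(rep("GLY", 7), 4, seed = 13))
  dp <- ens[[1]]
  l1 <- build_landscape(rep("GLY", 7), dp, 6, seed = 3,
                        include_design = TRUE)
  expect_equal(min(l1$rmsd), 0, tolerance = 1e-12)
  l2 <- build_landscape(rep("GLY", 7), dp, 6, seed = 3,
                        include_design = TRUE)
  expect_equal(as.data.frame(l1), as.data.frame(l2), tolerance = 1e-12)
  expect_true(all(l1$rmsd >= 0))
  expect_lte(nrow(l1), 7)
})

test_that("funnel selection applies thresholds, bounds and fallback", {
  rec <- structure(list(sequence = "SHA", report = list(ddg = -12),
                        method = 2), class = "DesignRecord")
  cand <- function(pnear, gap) list(
    record = rec,
    funnel = structure(list(pnear = pnear, energy_gap = gap,
                            min_energy_rmsd = 1, n = 10),
                       class = "FunnelStats"))
  cands <- list(cand(0.9, 5), cand(0.2, -3), cand(0.6, 1))
  ## pnear can never exceed 1: an impossible threshold empties the set
  none <- select_by_funnel(cands, policy = list(pnear_min = 1.01,
                                                gap_min = 0,
                                                fallback_interface = FALSE,
                                                ddg_max = -10))
  expect_length(none, 0)
  ## an all-pass policy returns the input records unchanged
  all_in <- select_by_funnel(cands, policy = list(pnear_min = 0,
                                                  gap_min = -Inf,
                                                  fallback_interface = FALSE,
                                                  ddg_max = -10))
  expect_length(all_in, length(cands))
  sel <- select_by_funnel(cands, policy = list(pnear_min = 0.5, gap_min = 0,
                                               fallback_interface = FALSE,
                                               ddg_max = -10))
  expect_length(sel, 2)
  ## interface fallback catches NA-gap candidates with good interfaces
  na_cand <- cand(0.1, NA)
  sel2 <- select_by_funnel(list(na_cand),
                           policy = list(pnear_min = 0.5, gap_min = 0,
                                         fallback_interface = TRUE,
                                         ddg_max = -10))
  expect_length(sel2, 1)
  expect_identical(attr(sel2, "reasons"), "interface-fallback")
})
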