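test_that("dihedral follows the IUPAC sign convention", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  ## +90 frozen from the cross-product oracle
  expect_equal(oracle_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                               c(1, 1, 1)), 90)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  ## random quadruples agree with the oracle
  set.seed(42)
  for (k in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               "coincide")
})

test_that("superpose recovers rigid transforms and is symmetric", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(a, a)$rmsd, 0, tolerance = 1e-12)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  b <- sweep(a %*% t(R), 2, c(3, -2, 5), `+`)
  fit <- superpose(a, b)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_transform(a, fit), b, tolerance = 1e-9)
  ## rmsd symmetry
  c2 <- a + matrix(rnorm(30, 0, 0.3), 10, 3)
  expect_equal(superpose(a, c2)$rmsd, superpose(c2, a)$rmsd,
               tolerance = 1e-9)
  expect_error(superpose(a[1:2, ], b[1:2, ]), "3 points")
  expect_error(superpose(a, b[1:5, ]), "cardinality")
})

test_that("chirality rule maps negative phi to L and positive to D", {
  expect_identical(chirality_for_phi(-60), "L")
  expect_identical(chirality_for_phi(60), "D")
  expect_identical(chirality_for_phi(0), "L")    # declared tie-break
  expect_identical(chirality_for_phi(180), "L")  # declared tie-break
  ## negating phi flips every assignment except ties
  phis <- setdiff(seq(-175, 175, by = 10), 0)
  flip <- c(L = "D", D = "L")
  expect_identical(unname(flip[chirality_for_phi(phis)]),
                   chirality_for_phi(-phis))
})

test_that("torsion bins are half-open and enumerate (360/width)^2 cells", {
  expect_error(bin_torsions(0, 0, width = 50), "divide")
  centers <- torsion_bin_centers(30)
  expect_equal(nrow(centers), 144)
  expect_equal(nrow(unique(centers[, c("phi_bin", "psi_bin")])), 144)
  b <- bin_torsions(-180 + 1e-9, -180 + 1e-9, 30)
  expect_equal(c(b$phi_bin, b$psi_bin), c(0, 0))
  expect_equal(bin_torsions(29.9, 0, 30)$phi_bin,
               bin_torsions(0.1, 0, 30)$phi_bin)
  expect_false(bin_torsions(30.1, 0, 30)$phi_bin ==
               bin_torsions(29.9, 0, 30)$phi_bin)
})

test_that("torsion preference surface has the declared symmetries", {
  ## glycine symmetric under (phi, psi) -> (-phi, -psi)
  expect_equal(rama_score("GLY", 60, 40), rama_score("GLY", -60, -40))
  ## L alpha-helical region at least as favorable as its mirror for L-Ala
  expect_lte(rama_score("ALA", -60, -45), rama_score("ALA", 60, 45))
  ## every D template scores as its L mirror, over a grid
  grid <- expand.grid(phi = seq(-150, 150, by = 60),
                      psi = seq(-150, 150, by = 60))
  for (code in c("ALA", "LEU", "ARG", "PRO", "SHA")) {
    d <- mirror_code(code)
    expect_equal(rama_score(d, grid$phi, grid$psi),
                 rama_score(code, -grid$phi, -grid$psi),
                 tolerance = 1e-12, label = code)
  }
})
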