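test_that("registry covers canonical L, D mirrors, glycine and the anchor", {
  for (code in canonical_codes()) {
    expect_true(template_exists(code), label = code)
    if (code != "GLY") expect_true(template_exists(mirror_code(code)),
                                   label = mirror_code(code))
  }
  expect_true(template_exists("SHA"))
  expect_identical(get_template("GLY")$chirality, "achiral")
  expect_identical(get_template("DAL")$chirality, "D")
  ## every code resolves to exactly one template with matching code
  for (code in list_templates())
    expect_identical(get_template(code)$code, code)
})

test_that("D templates are exact numeric mirrors of their L parents", {
  for (code in c("ALA", "LEU", "ARG", "SHA")) {
    L <- get_template(code); D <- get_template(mirror_code(code))
    expect_identical(L$atoms$name, D$atoms$name)
    for (k in seq_len(nrow(L$atoms))) {
      pl <- anchorext:::parse_torsion_expr(L$atoms$torsion[k])
      pd <- anchorext:::parse_torsion_expr(D$atoms$torsion[k])
      expect_equal(wrap_angle(pd$offset), wrap_angle(-pl$offset),
                   tolerance = 1e-12)
    }
    expect_equal(D$rotamers, -L$rotamers)
  }
})

test_that("the anchor side chain is a 5-methylene thiol reaching 6 bonds", {
  tpl <- get_template("SHA")
  side <- setdiff(tpl$atoms$name, c("N", "CA", "C", "O"))
  expect_identical(sum(tpl$atoms$element[tpl$atoms$name %in% side] == "C"), 5L)
  expect_identical(sum(tpl$atoms$element == "S"), 1L)
  expect_equal(bond_path_length(tpl, "CA", "SH"), 6)
})

test_that("build_peptide reproduces requested torsions to 1e-6 degrees", {
  p <- build_peptide(c("GLY", "GLY", "GLY"), c(-60, -45, 180))
  tt <- pose_torsions(p)
  expect_equal(tt$phi[2:3], c(-60, -60), tolerance = 1e-6)
  expect_equal(tt$psi, c(-45, -45, -45), tolerance = 1e-6)
  expect_equal(tt$omega[1:2], c(180, 180), tolerance = 1e-6)
  ## bond geometry matches the template ideals
  g <- anchorext:::BACKBONE_GEOM
  d <- sqrt(sum((get_atom(p, 1, "C") - get_atom(p, 2, "N"))^2))
  expect_equal(d, g$b_c_n, tolerance = 1e-9)
  expect_error(build_peptide(c("XXX")), "unknown residue")
})

test_that("mirrored sequences build exact mirror images", {
  tor <- rbind(c(-60, -45, 180), c(-80, 120, 180), c(-60, -40, 180))
  a <- build_peptide(c("ALA", "LEU", "SER"), tor)
  b <- build_peptide(c("DAL", "DLE", "DSN"), -tor)
  xa <- coords_matrix(pose_atoms(a, FALSE))
  xb <- coords_matrix(pose_atoms(b, FALSE))
  xb[, 3] <- -xb[, 3]  # reflect through z = 0
  expect_lt(superpose(xb, xa)$rmsd, 1e-6)
})

test_that("set_torsion moves only downstream atoms and round-trips", {
  p <- build_peptide(c("ALA", "SER", "LEU"), c(-60, -45, 180))
  p2 <- set_torsion(p, 2, "phi", 77)
  expect_identical(p$residues[[1]]$atoms, p2$residues[[1]]$atoms)
  expect_equal(pose_torsions(p2)$phi[2], 77, tolerance = 1e-6)
  ## other torsions untouched
  expect_equal(pose_torsions(p2)$psi[2], -45, tolerance = 1e-6)
  ## periodicity: +360 returns identical coordinates
  p3 <- set_torsion(p, 2, "psi", -45 + 360)
  expect_equal(coords_matrix(pose_atoms(p3, FALSE)),
               coords_matrix(pose_atoms(p, FALSE)), tolerance = 1e-9)
  ## chi round-trip and bounds
  p4 <- set_torsion(p, 2, "chi1", -72)
  expect_equal(pose_torsions(p4)$chis[[2]][1], -72, tolerance = 1e-6)
  expect_error(set_torsion(p, 2, "chi3", 10), "chi index out of range")
  ## bond lengths unchanged by the move
  d_before <- sqrt(sum((get_atom(p, 2, "CA") - get_atom(p, 2, "CB"))^2))
  d_after <- sqrt(sum((get_atom(p4, 2, "CA") - get_atom(p4, 2, "CB"))^2))
  expect_equal(d_after, d_before, tolerance = 1e-9)
})

test_that("template registry text format round-trips", {
  reg <- list(ALA = get_template("ALA"), SHA = get_template("SHA"),
              DAL = get_template("DAL"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_template_registry(reg, path)
  back <- read_template_registry(path)
  expect_setequal(names(back), names(reg))
  for (nm in names(reg)) {
    expect_identical(back[[nm]]$atoms$name, reg[[nm]]$atoms$name)
    expect_equal(back[[nm]]$atoms$bond, reg[[nm]]$atoms$bond,
                 tolerance = 1e-3)
    expect_identical(back[[nm]]$chi_atoms, reg[[nm]]$chi_atoms)
  }
  ## registering a parsed template (with mirror) makes it buildable
  tpl <- back$SHA; tpl$code <- "SH2"
  register_template(tpl, mirror = TRUE, mirror_code = "DS2")
  expect_true(template_exists("SH2") && template_exists("DS2"))
  p <- build_peptide(c("GLY", "SH2"), c(-60, -45, 180))
  expect_equal(pose_size(p), 2)
})

test_that("PDB round-trip preserves coordinates and residue codes", {
  p <- build_peptide(c("ALA", "SHA", "TRP", "GLY", "DAL"), c(-60, -45, 180))
  p$zinc <- list(list(position = c(5, 5, 5), target = 2.3))
  p$waters <- list(positions = rbind(c(1, 2, 3), c(4, 5, 6)),
                   structural = c(TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, path)
  q <- read_pdb(path)
  expect_identical(pose_sequence(q), pose_sequence(p))
  expect_lt(max(abs(coords_matrix(pose_atoms(q)) -
                    coords_matrix(pose_atoms(p)))), 1e-3 + 1e-9)
  expect_equal(length(q$zinc), 1)
  expect_equal(nrow(q$waters$positions), 2)
  ## D residue written under its registry D code
  expect_true(any(grepl("DAL", readLines(path))))
})

test_that("cyclic peptides are written without internal TER records", {
  ens <- sample_closed_ensemble(rep("GLY", 7), 1, seed = 5,
                                max_attempts = 600)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens[[1]], path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  ter_lines <- grep("^TER", lines)
  expect_true(all(ter_lines > max(atom_lines)))
})

test_that("PDB reader handles hetero-only files and error modes", {
  zn_file <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 ZN    ZN A   1       1.000   2.000   3.000  1.00  0.00          ZN",
    "END"), zn_file)
  p <- read_pdb(zn_file)
  expect_equal(pose_size(p), 0)
  expect_equal(length(p$zinc), 1)
  expect_equal(p$zinc[[1]]$position, c(1, 2, 3))
  ## malformed coordinate columns -> parse error with line number
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      bad.00   0.000   0.000"),
             bad)
  expect_error(read_pdb(bad), "line 1")
  ## unknown residue dropped quietly, rejected in strict mode
  unk <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  XYZ A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), unk)
  expect_equal(pose_size(read_pdb(unk)), 0)
  expect_error(read_pdb(unk, strict = TRUE), "strict")
  ## atom names longer than 4 characters are unwritable
  p2 <- build_peptide("ALA", c(-60, -45, 180))
  rownames(p2$residues[[1]]$atoms)[5] <- "CBXXX"
  expect_error(write_pdb(p2, withr::local_tempfile()), "longer than 4")
})
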