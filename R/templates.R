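## Residue chemistry registry.
##
## Every residue type is defined in internal coordinates: one atom per row
## with three reference atoms, a bond length (A), bond angle (deg) and
## torsion (deg or a symbolic expression). Reference atoms prefixed "-"
## live in the preceding residue; symbolic torsions phi/psi/omega/chiK
## (optionally +/- an offset) are bound at build time. Heavy atoms only;
## hydrogen-bond chemistry is carried by the polar role column
## (donor / acceptor / both / none; donors are the heavy atoms bearing
## implicit H).
##
## D residues are generated as exact mirrors of their L parents (all
## numeric torsions negated, rotamer chi signs flipped) and registered
## under the standard D 3-letter codes (DAL, DAR, ...). The anchor residue
## SHA (2S-2-amino-7-sulfanylheptanoic acid) carries a 5-methylene thiol
## side chain that reaches the catalytic zinc.

BACKBONE_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.328, b_c_o = 1.231,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, b_ca_cb = 1.530, cb_improper = -122.6
)

.d_code_map <- c(
  ALA = "DAL", ARG = "DAR", ASN = "DSG", ASP = "DAS", CYS = "DCY",
  GLN = "DGN", GLU = "DGL", HIS = "DHI", ILE = "DIL", LEU = "DLE",
  LYS = "DLY", MET = "MED", PHE = "DPN", PRO = "DPR", SER = "DSN",
  THR = "DTH", TRP = "DTR", TYR = "DTY", VAL = "DVA", SHA = "DSH"
)

#' The 20 canonical L amino-acid codes
#' @return character vector of 3-letter codes
#' @export
canonical_codes <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' D-variant code of an L code (and vice versa)
#' @param code 3-letter residue code
#' @return the mirror code; achiral codes map to themselves
#' @export
mirror_code <- function(code) {
  if (code %in% names(.d_code_map)) return(unname(.d_code_map[code]))
  rev_map <- setNames(names(.d_code_map), .d_code_map)
  if (code %in% names(rev_map)) return(unname(rev_map[code]))
  code  # achiral (GLY)
}

atom_row <- function(name, element, ref1, ref2, ref3, bond, angle, torsion,
                     role = "none") {
  data.frame(name = name, element = element, ref1 = ref1, ref2 = ref2,
             ref3 = ref3, bond = bond, angle = angle, torsion = torsion,
             role = role, stringsAsFactors = FALSE)
}

backbone_rows <- function(n_role = "donor", with_cb = TRUE) {
  g <- BACKBONE_GEOM
  rows <- rbind(
    atom_row("N", "N", "-C", "-CA", "-N", g$b_c_n, g$a_ca_c_n, "psi", n_role),
    atom_row("CA", "C", "N", "-C", "-CA", g$b_n_ca, g$a_c_n_ca, "omega"),
    atom_row("C", "C", "CA", "N", "-C", g$b_ca_c, g$a_n_ca_c, "phi"),
    atom_row("O", "O", "C", "CA", "N", g$b_c_o, g$a_ca_c_o, "psi-180",
             "acceptor"))
  if (with_cb)
    rows <- rbind(rows, atom_row("CB", "C", "CA", "N", "C", g$b_ca_cb,
                                 g$a_n_ca_cb, as.character(g$cb_improper)))
  rows
}

.sidechain_defs <- function() {
  a <- atom_row
  list(
    ALA = NULL,
    SER = a("OG", "O", "CB", "CA", "N", 1.42, 110.8, "chi1", "both"),
    CYS = a("SG", "S", "CB", "CA", "N", 1.81, 113.8, "chi1", "donor"),
    THR = rbind(a("OG1", "O", "CB", "CA", "N", 1.43, 109.6, "chi1", "both"),
                a("CG2", "C", "CB", "CA", "N", 1.52, 110.5, "chi1-120")),
    VAL = rbind(a("CG1", "C", "CB", "CA", "N", 1.53, 110.5, "chi1"),
                a("CG2", "C", "CB", "CA", "N", 1.53, 110.5, "chi1+120")),
    LEU = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 116.3, "chi1"),
                a("CD1", "C", "CG", "CB", "CA", 1.53, 110.7, "chi2"),
                a("CD2", "C", "CG", "CB", "CA", 1.53, 110.7, "chi2+120")),
    ILE = rbind(a("CG1", "C", "CB", "CA", "N", 1.53, 110.4, "chi1"),
                a("CG2", "C", "CB", "CA", "N", 1.53, 110.5, "chi1-120"),
                a("CD1", "C", "CG1", "CB", "CA", 1.53, 113.8, "chi2")),
    ASP = rbind(a("CG", "C", "CB", "CA", "N", 1.52, 112.6, "chi1"),
                a("OD1", "O", "CG", "CB", "CA", 1.25, 118.4, "chi2",
                  "acceptor"),
                a("OD2", "O", "CG", "CB", "CA", 1.25, 118.4, "chi2+180",
                  "acceptor")),
    ASN = rbind(a("CG", "C", "CB", "CA", "N", 1.52, 112.6, "chi1"),
                a("OD1", "O", "CG", "CB", "CA", 1.23, 120.8, "chi2",
                  "acceptor"),
                a("ND2", "N", "CG", "CB", "CA", 1.33, 116.4, "chi2+180",
                  "donor")),
    GLU = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 114.1, "chi1"),
                a("CD", "C", "CG", "CB", "CA", 1.52, 112.6, "chi2"),
                a("OE1", "O", "CD", "CG", "CB", 1.25, 118.4, "chi3",
                  "acceptor"),
                a("OE2", "O", "CD", "CG", "CB", 1.25, 118.4, "chi3+180",
                  "acceptor")),
    GLN = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 114.1, "chi1"),
                a("CD", "C", "CG", "CB", "CA", 1.52, 112.6, "chi2"),
                a("OE1", "O", "CD", "CG", "CB", 1.23, 120.8, "chi3",
                  "acceptor"),
                a("NE2", "N", "CD", "CG", "CB", 1.33, 116.4, "chi3+180",
                  "donor")),
    LYS = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 114.1, "chi1"),
                a("CD", "C", "CG", "CB", "CA", 1.53, 111.3, "chi2"),
                a("CE", "C", "CD", "CG", "CB", 1.53, 111.3, "chi3"),
                a("NZ", "N", "CE", "CD", "CG", 1.47, 111.2, "chi4",
                  "donor")),
    ARG = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 114.1, "chi1"),
                a("CD", "C", "CG", "CB", "CA", 1.53, 111.3, "chi2"),
                a("NE", "N", "CD", "CG", "CB", 1.46, 111.5, "chi3",
                  "donor"),
                a("CZ", "C", "NE", "CD", "CG", 1.33, 124.2, "chi4"),
                a("NH1", "N", "CZ", "NE", "CD", 1.33, 120.0, "0", "donor"),
                a("NH2", "N", "CZ", "NE", "CD", 1.33, 120.0, "180",
                  "donor")),
    MET = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 114.1, "chi1"),
                a("SD", "S", "CG", "CB", "CA", 1.81, 112.7, "chi2"),
                a("CE", "C", "SD", "CG", "CB", 1.79, 100.9, "chi3")),
    PHE = rbind(a("CG", "C", "CB", "CA", "N", 1.50, 113.8, "chi1"),
                a("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2"),
                a("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2+180"),
                a("CE1", "C", "CD1", "CG", "CB", 1.39, 121.0, "180"),
                a("CE2", "C", "CD2", "CG", "CB", 1.39, 121.0, "180"),
                a("CZ", "C", "CE1", "CD1", "CG", 1.39, 120.0, "0")),
    TYR = rbind(a("CG", "C", "CB", "CA", "N", 1.50, 113.8, "chi1"),
                a("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2"),
                a("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, "chi2+180"),
                a("CE1", "C", "CD1", "CG", "CB", 1.39, 121.0, "180"),
                a("CE2", "C", "CD2", "CG", "CB", 1.39, 121.0, "180"),
                a("CZ", "C", "CE1", "CD1", "CG", 1.39, 120.0, "0"),
                a("OH", "O", "CZ", "CE1", "CD1", 1.38, 119.9, "180",
                  "both")),
    HIS = rbind(a("CG", "C", "CB", "CA", "N", 1.49, 113.7, "chi1"),
                a("ND1", "N", "CG", "CB", "CA", 1.38, 122.8, "chi2",
                  "acceptor"),
                a("CD2", "C", "CG", "CB", "CA", 1.35, 129.7, "chi2+180"),
                a("CE1", "C", "ND1", "CG", "CB", 1.32, 108.6, "180"),
                a("NE2", "N", "CD2", "CG", "CB", 1.37, 107.0, "180",
                  "donor")),
    TRP = rbind(a("CG", "C", "CB", "CA", "N", 1.50, 113.6, "chi1"),
                a("CD1", "C", "CG", "CB", "CA", 1.37, 126.9, "chi2"),
                a("CD2", "C", "CG", "CB", "CA", 1.43, 126.7, "chi2+180"),
                a("NE1", "N", "CD1", "CG", "CB", 1.38, 110.2, "180",
                  "donor"),
                a("CE2", "C", "CD2", "CG", "CB", 1.41, 107.2, "180"),
                a("CE3", "C", "CD2", "CG", "CB", 1.40, 133.9, "0"),
                a("CZ2", "C", "CE2", "CD2", "CG", 1.40, 122.4, "180"),
                a("CZ3", "C", "CE3", "CD2", "CG", 1.39, 118.7, "180"),
                a("CH2", "C", "CZ2", "CE2", "CD2", 1.37, 117.5, "180")),
    PRO = rbind(a("CG", "C", "CB", "CA", "N", 1.49, 104.5, "chi1"),
                a("CD", "C", "CG", "CB", "CA", 1.51, 106.1, "chi2")),
    ## anchor: 5-methylene chain ending in a thiol (CA->S path = 6 bonds)
    SHA = rbind(a("CG", "C", "CB", "CA", "N", 1.53, 114.1, "chi1"),
                a("CD", "C", "CG", "CB", "CA", 1.53, 111.3, "chi2"),
                a("CE", "C", "CD", "CG", "CB", 1.53, 111.3, "chi3"),
                a("CZ", "C", "CE", "CD", "CG", 1.53, 111.3, "chi4"),
                a("SH", "S", "CZ", "CE", "CD", 1.82, 112.0, "chi5",
                  "donor"))
  )
}

parse_torsion_expr <- function(s) {
  s <- trimws(s)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(list(kind = "fixed", idx = 0L, offset = num))
  m <- regmatches(s, regexec("^(phi|psi|omega|chi([0-9]+))([+-][0-9.]+)?$", s))[[1]]
  if (length(m) == 0) stop("bad torsion expression: ", s)
  kind <- if (startsWith(m[2], "chi")) "chi" else m[2]
  idx <- if (kind == "chi") as.integer(m[3]) else 0L
  offset <- if (m[4] == "") 0 else as.numeric(m[4])
  list(kind = kind, idx = idx, offset = offset)
}

negate_torsion_expr <- function(s) {
  p <- parse_torsion_expr(s)
  if (p$kind == "fixed") return(as.character(-p$offset))
  base <- if (p$kind == "chi") paste0("chi", p$idx) else p$kind
  if (p$offset == 0) return(base)
  off <- wrap_angle(-p$offset)
  paste0(base, ifelse(off >= 0, "+", ""), off)
}

make_template <- function(code, chirality, atoms, base_code = code) {
  rownames(atoms) <- NULL
  ## chi definitions from the first atom tied to each chi index
  chi_atoms <- list()
  for (i in seq_len(nrow(atoms))) {
    p <- parse_torsion_expr(atoms$torsion[i])
    if (p$kind == "chi" && p$offset == 0)
      chi_atoms[[p$idx]] <- c(atoms$ref3[i], atoms$ref2[i], atoms$ref1[i],
                              atoms$name[i])
  }
  n_chi <- length(chi_atoms)
  rotamers <- default_rotamers(code, base_code, n_chi)
  structure(list(code = code, base_code = base_code, chirality = chirality,
                 atoms = atoms, chi_atoms = chi_atoms, n_chi = n_chi,
                 rotamers = rotamers),
            class = "ResidueTemplate")
}

## chi sets enumerated at -60/60/180 per chi (first three chis; deeper
## chis start extended), a deliberate desk-scale stand-in for a
## statistical rotamer library. Proline's ring limits chi1/chi2.
default_rotamers <- function(code, base_code, n_chi) {
  if (n_chi == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  if (base_code == "PRO")
    return(matrix(c(25, -35, -25, 35), nrow = 2, byrow = TRUE))
  k <- min(n_chi, 3)
  g <- as.matrix(expand.grid(rep(list(c(-60, 60, 180)), k)))
  if (n_chi > k)
    g <- cbind(g, matrix(180, nrow = nrow(g), ncol = n_chi - k))
  dimnames(g) <- NULL
  g
}

mirror_template <- function(tpl, new_code) {
  atoms <- tpl$atoms
  atoms$torsion <- vapply(atoms$torsion, negate_torsion_expr, character(1))
  out <- make_template(new_code, "D", atoms, base_code = tpl$base_code)
  out$rotamers <- -tpl$rotamers
  out
}

build_builtin_registry <- function() {
  defs <- .sidechain_defs()
  reg <- list()
  for (code in names(defs)) {
    n_role <- if (code == "PRO") "none" else "donor"
    atoms <- rbind(backbone_rows(n_role, with_cb = TRUE), defs[[code]])
    tpl <- make_template(code, "L", atoms)
    reg[[code]] <- tpl
    dcode <- unname(.d_code_map[code])
    reg[[dcode]] <- mirror_template(tpl, dcode)
  }
  reg[["GLY"]] <- make_template(
    "GLY", "achiral", backbone_rows("donor", with_cb = FALSE))
  reg
}

ensure_registry <- function() {
  if (is.null(.ax_env$templates))
    .ax_env$templates <- build_builtin_registry()
  invisible(.ax_env$templates)
}

#' Look up a residue template by code
#' @param code 3-letter residue code (L, D or non-canonical)
#' @return a `ResidueTemplate`
#' @export
get_template <- function(code) {
  reg <- ensure_registry()
  tpl <- reg[[code]]
  if (is.null(tpl)) stop("unknown residue code: ", code)
  tpl
}

#' Is a residue code registered?
#' @param code 3-letter residue code
#' @return logical
#' @export
template_exists <- function(code) {
  code %in% names(ensure_registry())
}

#' All registered residue codes
#' @return character vector
#' @export
list_templates <- function() names(ensure_registry())

#' Register a residue template
#'
#' Adds a (typically non-canonical) residue definition to the registry.
#' If `mirror` is TRUE and a mirror code can be derived, the D mirror is
#' registered too.
#'
#' @param tpl a `ResidueTemplate` (see [read_template_registry()] or
#'   `make_template`)
#' @param mirror also register the mirrored variant under `mirror_code`
#' @param mirror_code code for the mirrored variant
#' @return invisibly, the registered template
#' @export
register_template <- function(tpl, mirror = FALSE,
                              mirror_code = paste0("D", substr(tpl$code, 1, 2))) {
  ensure_registry()
  .ax_env$templates[[tpl$code]] <- tpl
  if (mirror)
    .ax_env$templates[[mirror_code]] <- mirror_template(tpl, mirror_code)
  invisible(tpl)
}

#' Read residue templates from a registry text file
#'
#' Format: one `residue CODE CHIRALITY` header per block followed by
#' `atom name element ref1 ref2 ref3 bond angle torsion role` lines.
#' Reference atoms prefixed `-` live in the preceding residue; torsions
#' are degrees or symbolic (`phi`, `psi`, `omega`, `chiK`, with an
#' optional `+/-offset`).
#'
#' @param path file path
#' @return named list of `ResidueTemplate` objects
#' @export
read_template_registry <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur_code <- NULL; cur_chir <- NULL; cur_atoms <- NULL
  flush <- function() {
    if (!is.null(cur_code))
      out[[cur_code]] <<- make_template(cur_code, cur_chir, cur_atoms)
  }
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (f[1] == "residue") {
      flush()
      cur_code <- f[2]; cur_chir <- f[3]; cur_atoms <- NULL
    } else if (f[1] == "atom") {
      if (length(f) != 10) stop("bad atom line: ", ln)
      cur_atoms <- rbind(cur_atoms, atom_row(f[2], f[3], f[4], f[5], f[6],
                                             as.numeric(f[7]),
                                             as.numeric(f[8]), f[9], f[10]))
    } else stop("unrecognized registry line: ", ln)
  }
  flush()
  out
}

#' Write residue templates to a registry text file
#' @param templates named list of `ResidueTemplate` objects
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_template_registry <- function(templates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tpl in templates) {
    writeLines(sprintf("residue %s %s", tpl$code, tpl$chirality), con)
    for (i in seq_len(nrow(tpl$atoms))) {
      a <- tpl$atoms[i, ]
      writeLines(sprintf("atom %s %s %s %s %s %.4g %.5g %s %s",
                         a$name, a$element, a$ref1, a$ref2, a$ref3,
                         a$bond, a$angle, a$torsion, a$role), con)
    }
  }
  invisible(path)
}

#' @export
print.ResidueTemplate <- function(x, ...) {
  cat(sprintf("ResidueTemplate %s (%s, %d atoms, %d chi)\n",
              x$code, x$chirality, nrow(x$atoms), x$n_chi))
  invisible(x)
}
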