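## Structural validation against experimentally determined coordinates.
## These helpers take local PDB file paths (no downloads) and make the
## three standard measurements used to validate designed zinc-binding
## macrocycles: receptor Calpha shift upon binding, zinc-thiol
## coordination distance, and a backbone phi of interest.

#' Calpha RMSD between a bound receptor and its apo structure
#'
#' Matches Calpha atoms by residue number between the receptor chain of
#' the complex and the apo structure, superposes them (Kabsch) and
#' returns the RMSD over the matched set.
#'
#' @param complex_path PDB file of the complex
#' @param apo_path PDB file of the apo receptor
#' @param chain_complex,chain_apo receptor chain ids
#' @return list: rmsd (A), n_atoms matched
#' @export
ca_rmsd_vs_apo <- function(complex_path, apo_path, chain_complex = "A",
                           chain_apo = "A") {
  px <- bio3d::read.pdb(complex_path, verbose = FALSE)
  pa <- bio3d::read.pdb(apo_path, verbose = FALSE)
  cax <- px$atom[px$atom$elety == "CA" & px$atom$chain == chain_complex &
                 px$atom$type == "ATOM", ]
  caa <- pa$atom[pa$atom$elety == "CA" & pa$atom$chain == chain_apo &
                 pa$atom$type == "ATOM", ]
  common <- intersect(cax$resno, caa$resno)
  if (length(common) < 3) stop("fewer than 3 matched Calpha atoms")
  mx <- as.matrix(cax[match(common, cax$resno), c("x", "y", "z")])
  ma <- as.matrix(caa[match(common, caa$resno), c("x", "y", "z")])
  fit <- superpose(mx, ma)
  list(rmsd = fit$rmsd, n_atoms = length(common))
}

#' Zinc-sulfur coordination distance in a structure
#'
#' Distance from each zinc to the nearest sulfur atom (A).
#'
#' @param path PDB file
#' @return numeric vector, one value per zinc
#' @export
zinc_sulfur_distance <- function(path) {
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  zn <- at[toupper(trimws(at$elety)) == "ZN", , drop = FALSE]
  s <- at[grepl("^S", trimws(at$elety)) &
          !trimws(at$elety) %in% c("SE"), , drop = FALSE]
  if (nrow(zn) == 0) stop("no zinc in structure")
  if (nrow(s) == 0) stop("no sulfur atoms in structure")
  apply(zn[, c("x", "y", "z")], 1, function(z)
    min(sqrt(colSums((t(as.matrix(s[, c("x", "y", "z")])) -
                      as.numeric(z))^2))))
}

#' Backbone phi of one residue in a PDB file
#'
#' @param path PDB file
#' @param chain chain id
#' @param resno residue number
#' @return phi in degrees
#' @export
residue_phi <- function(path, chain, resno) {
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom[p$atom$chain == chain, ]
  pick <- function(rn, nm) {
    row <- at[at$resno == rn & trimws(at$elety) == nm, , drop = FALSE]
    if (nrow(row) == 0) stop("missing atom ", nm, " in residue ", rn)
    as.numeric(row[1, c("x", "y", "z")])
  }
  prev <- max(at$resno[at$resno < resno & trimws(at$elety) == "C"])
  dihedral(pick(prev, "C"), pick(resno, "N"), pick(resno, "CA"),
           pick(resno, "C"))
}
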