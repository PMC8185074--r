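## Surrogate all-atom energy. A documented stand-in scoring function on a
## kcal/mol-like scale, additive over terms:
##   lj_rep / lj_atr  split 12-6 Lennard-Jones (minimum at vdW contact)
##   hb               distance-only hydrogen-bond well (donor-acceptor)
##   elec             screened-Coulomb with rule-based charges
##   rama             backbone torsion preference (see rama_score)
##   zn               harmonic restraint pulling a ligand thiol S to the
##                    zinc target coordination distance (2.3 A)
##   closure          harmonic penalty on cyclic closure-bond geometry
## Zinc atoms are excluded from the pairwise terms; their chemistry is
## entirely in the restraint. Waters enter the pairwise terms as rigid
## oxygen sites that can donate and accept.

energy_terms_pairwise <- function(atoms_df, excl, active, cfg) {
  coords <- coords_matrix(atoms_df)
  role_code <- match(atoms_df$role, c("none", "donor", "acceptor", "both")) - 1L
  pair_energy_cpp(coords, atoms_df$radius, atoms_df$charge,
                  as.integer(role_code), excl, active,
                  cutoff = cfg$nb_cutoff, eps_lj = cfg$lj_eps,
                  hb_ideal = cfg$hb_ideal, hb_sd = cfg$hb_sd,
                  hb_max = cfg$hb_max, hb_depth = cfg$hb_depth,
                  elec_eps = cfg$elec_eps, elec_kappa = cfg$elec_kappa)
}

## harmonic restraint of each zinc to the nearest ligand thiol sulfur
## (sulfur atoms on chains other than the receptor's)
zinc_term <- function(pose, atoms_df, cfg, receptor_chains = NULL) {
  if (length(pose$zinc) == 0) return(0)
  s_rows <- atoms_df$element == "S"
  if (!is.null(receptor_chains))
    s_rows <- s_rows & !(atoms_df$chain %in% receptor_chains)
  if (!any(s_rows)) return(0)
  s_xyz <- coords_matrix(atoms_df[s_rows, , drop = FALSE])
  tot <- 0
  for (zn in pose$zinc) {
    d <- sqrt(colSums((t(s_xyz) - zn$position)^2))
    tot <- tot + (min(d) - zn$target)^2
  }
  tot
}

rama_term <- function(pose) {
  tt <- pose_torsions(pose)
  ok <- !is.na(tt$phi) & !is.na(tt$psi)
  if (!any(ok)) return(0)
  sum(mapply(function(code, phi, psi) rama_score(code, phi, psi),
             tt$code[ok], tt$phi[ok], tt$psi[ok]))
}

#' Closure-bond geometry of a cyclic pose
#'
#' @param pose a `Pose` with a cyclic chain
#' @param chain chain id; default: the first cyclic chain
#' @return list with `length` (C(n)-N(1), A), `angle_c` (CA-C-N, deg),
#'   `angle_n` (C-N-CA, deg), `omega` (CA-C-N-CA, deg)
#' @export
closure_geometry <- function(pose, chain = NULL) {
  if (is.null(chain)) {
    cyc <- cyclic_chains(pose)
    chain <- if (length(cyc)) cyc[1] else pose$chain[1]
  }
  members <- which(pose$chain == chain)
  n <- max(members); one <- min(members)
  Cn <- get_atom(pose, n, "C"); CAn <- get_atom(pose, n, "CA")
  N1 <- get_atom(pose, one, "N"); CA1 <- get_atom(pose, one, "CA")
  list(length = sqrt(sum((Cn - N1)^2)),
       angle_c = bond_angle(CAn, Cn, N1),
       angle_n = bond_angle(Cn, N1, CA1),
       omega = dihedral(CAn, Cn, N1, CA1))
}

#' Does a cyclic pose satisfy the closure tolerance?
#' @param pose a cyclic `Pose`
#' @param cfg configuration (uses `ideal_cn`, `closure_tol_len`,
#'   `closure_tol_ang`)
#' @return logical
#' @export
closure_valid <- function(pose, cfg = ax_config()) {
  g <- closure_geometry(pose)
  abs(g$length - cfg$ideal_cn) <= cfg$closure_tol_len &&
    abs(g$angle_c - BACKBONE_GEOM$a_ca_c_n) <= cfg$closure_tol_ang &&
    abs(g$angle_n - BACKBONE_GEOM$a_c_n_ca) <= cfg$closure_tol_ang
}

closure_term <- function(pose, cfg) {
  tot <- 0
  for (ch in cyclic_chains(pose)) {
    if (sum(pose$chain == ch) < 3) next
    g <- closure_geometry(pose, ch)
    tot <- tot + (g$length - cfg$ideal_cn)^2 +
      0.01 * (g$angle_c - BACKBONE_GEOM$a_ca_c_n)^2 +
      0.01 * (g$angle_n - BACKBONE_GEOM$a_c_n_ca)^2 +
      0.005 * wrap_angle(g$omega - 180)^2
  }
  tot
}

#' Surrogate total energy of a pose
#'
#' Deterministic, additive over terms; the per-term breakdown is attached
#' as attribute `"breakdown"`.
#'
#' @param pose a `Pose`
#' @param cfg configuration (weights `w_*` and nonbonded parameters)
#' @param receptor_chains chains owning the zinc sites (their own S atoms
#'   are not pulled by the restraint); defaults to all but the last chain
#' @return numeric energy
#' @export
total_energy <- function(pose, cfg = ax_config(), receptor_chains = NULL) {
  atoms_df <- pose_atoms(pose, include_het = TRUE)
  atoms_df <- atoms_df[atoms_df$element != "ZN", , drop = FALSE]
  poly <- pose_atoms(pose, include_het = FALSE)
  excl <- bonded_exclusions(pose, poly)
  active <- rep(TRUE, nrow(atoms_df))
  pw <- energy_terms_pairwise(atoms_df, excl, active, cfg)
  if (is.null(receptor_chains)) {
    ch <- unique(pose$chain)
    receptor_chains <- if (length(ch) > 1) ch[-length(ch)] else character(0)
  }
  terms <- c(
    lj_rep = cfg$w_rep * pw[["lj_rep"]],
    lj_atr = cfg$w_atr * pw[["lj_atr"]],
    hb = cfg$w_hb * pw[["hb"]],
    elec = cfg$w_elec * pw[["elec"]],
    rama = cfg$w_rama * rama_term(pose),
    zn = cfg$w_zn * zinc_term(pose, atoms_df, cfg, receptor_chains),
    closure = cfg$w_closure * closure_term(pose, cfg))
  e <- sum(terms)
  attr(e, "breakdown") <- terms
  e
}

#' Binding energy gap of a peptide-receptor complex
#'
#' `E(complex) - E(receptor) - E(peptide)`, the surrogate analog of an
#' interface ddG. With `repack = FALSE` the separated-state coordinates
#' are identical to the bound state, so the value isolates the
#' inter-chain terms (plus the zinc restraint, which only exists in the
#' complex). With `repack = TRUE` the unbound peptide's side chains are
#' re-optimized (best rotamer per residue) before scoring.
#'
#' @param complex_pose `Pose` containing receptor and peptide chains
#' @param peptide_chain chain id of the peptide
#' @param repack re-optimize unbound peptide side chains
#' @param cfg configuration
#' @return numeric (surrogate kcal/mol-like)
#' @export
ddg_bind <- function(complex_pose, peptide_chain = "P", repack = FALSE,
                     cfg = ax_config()) {
  if (!peptide_chain %in% complex_pose$chain)
    stop("complex has no chain ", peptide_chain)
  receptor_chains <- setdiff(unique(complex_pose$chain), peptide_chain)
  if (length(receptor_chains) == 0)
    stop("complex has no receptor chain distinct from ", peptide_chain)
  pep <- pose_chain_subset(complex_pose, peptide_chain, keep_het = FALSE)
  rec <- pose_chain_subset(complex_pose, receptor_chains, keep_het = TRUE)
  if (repack) pep <- repack_side_chains(pep, cfg)
  e_cx <- total_energy(complex_pose, cfg, receptor_chains)
  e_rec <- total_energy(rec, cfg, receptor_chains)
  e_pep <- total_energy(pep, cfg, character(0))
  as.numeric(e_cx) - as.numeric(e_rec) - as.numeric(e_pep)
}

## greedy best-rotamer pass over all residues of a (small) pose
repack_side_chains <- function(pose, cfg = ax_config()) {
  for (i in seq_len(pose_size(pose))) {
    tpl <- get_template(pose$residues[[i]]$code)
    if (tpl$n_chi == 0) next
    best <- NULL; best_e <- Inf
    for (r in seq_len(nrow(tpl$rotamers))) {
      cand <- pose
      cand$residues[[i]] <- build_side_chain(cand$residues[[i]],
                                             tpl$rotamers[r, ])
      e <- as.numeric(total_energy(cand, cfg, character(0)))
      if (e < best_e) { best_e <- e; best <- cand }
    }
    pose <- best
  }
  pose
}
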