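## Torsion-space local minimization of the surrogate energy. The movable
## chain is rebuilt from ideal internal coordinates at each step (so
## geometry stays ideal by construction), rigidly re-anchored onto a
## reference residue, and scored against the rigid environment.

## compiled state reused across objective evaluations
minimize_state <- function(pose, movable_chain, cfg, anchor_resno) {
  idx <- which(pose$chain == movable_chain)
  if (length(idx) == 0) stop("no residues in chain ", movable_chain)
  codes <- pose_sequence(pose)[idx]
  cc <- compile_chain(codes)
  tt <- pose_torsions(pose)[idx, ]
  tor <- cbind(ifelse(is.na(tt$phi), -60, tt$phi),
               ifelse(is.na(tt$psi), -45, tt$psi),
               ifelse(is.na(tt$omega), 180, tt$omega))
  tv <- torsion_vector(cc, tor, tt$chis)
  atoms_df <- pose_atoms(pose, include_het = TRUE)
  atoms_df <- atoms_df[atoms_df$element != "ZN", , drop = FALSE]
  poly <- pose_atoms(pose, include_het = FALSE)
  excl <- bonded_exclusions(pose, poly)
  chain_rows <- which(atoms_df$chain == movable_chain)
  if (length(chain_rows) != nrow(cc$refs))
    stop("chain atoms do not match template atoms; cannot minimize")
  anchor_local <- match(anchor_resno, idx)
  ## reference backbone of the anchor residue, for rigid re-anchoring
  ref_bb <- rbind(get_atom(pose, anchor_resno, "N"),
                  get_atom(pose, anchor_resno, "CA"),
                  get_atom(pose, anchor_resno, "C"))
  bb_rows <- which(cc$atom_res == anchor_local &
                   cc$atom_names %in% c("N", "CA", "C"))
  role_code <- match(atoms_df$role, c("none", "donor", "acceptor", "both")) - 1L
  is_cyc <- movable_chain %in% cyclic_chains(pose)
  list(pose = pose, cc = cc, tv = tv, atoms_df = atoms_df, excl = excl,
       chain_rows = chain_rows, ref_bb = ref_bb, bb_rows = bb_rows,
       role_code = role_code, cfg = cfg, idx = idx, is_cyc = is_cyc,
       coords_all = coords_matrix(atoms_df),
       active = atoms_df$chain == movable_chain,
       s_local = which(cc$atom_names %in% c("SH", "SG", "SD")),
       zn = pose$zinc)
}

chain_coords_at <- function(st, tv) {
  coords <- ic_build_cpp(st$cc$refs, st$cc$geom, st$cc$tor_idx, tv,
                         st$cc$coords_init)
  tr <- superpose(coords[st$bb_rows, , drop = FALSE], st$ref_bb)
  apply_transform(coords, tr)
}

minimize_objective <- function(st, tv, start_coords = NULL, w_cst = 0) {
  cfg <- st$cfg
  coords <- chain_coords_at(st, tv)
  all_xyz <- st$coords_all
  all_xyz[st$chain_rows, ] <- coords
  pw <- pair_energy_cpp(all_xyz, st$atoms_df$radius, st$atoms_df$charge,
                        as.integer(st$role_code), st$excl, st$active,
                        cutoff = cfg$nb_cutoff, eps_lj = cfg$lj_eps,
                        hb_ideal = cfg$hb_ideal, hb_sd = cfg$hb_sd,
                        hb_max = cfg$hb_max, hb_depth = cfg$hb_depth,
                        elec_eps = cfg$elec_eps, elec_kappa = cfg$elec_kappa)
  e <- cfg$w_rep * pw[["lj_rep"]] + cfg$w_atr * pw[["lj_atr"]] +
    cfg$w_hb * pw[["hb"]] + cfg$w_elec * pw[["elec"]]
  ## rama over movable residues (torsion values are at hand)
  n <- length(st$cc$codes)
  for (i in seq_len(n)) {
    phi <- tv[sprintf("phi_%d", i)]; psi <- tv[sprintf("psi_%d", i)]
    if (i == 1) {
      if (!st$is_cyc) next
      last_c <- coords[which(st$cc$atom_res == n &
                             st$cc$atom_names == "C"), ]
      phi <- dihedral_cpp(last_c,
                          coords[which(st$cc$atom_res == 1 &
                                       st$cc$atom_names == "N"), ],
                          coords[which(st$cc$atom_res == 1 &
                                       st$cc$atom_names == "CA"), ],
                          coords[which(st$cc$atom_res == 1 &
                                       st$cc$atom_names == "C"), ])
    }
    e <- e + cfg$w_rama * rama_score(st$cc$codes[i], phi, psi)
  }
  ## zinc restraint to movable-chain sulfurs
  if (length(st$zn) && length(st$s_local)) {
    s_xyz <- coords[st$s_local, , drop = FALSE]
    for (zn in st$zn) {
      d <- sqrt(colSums((t(s_xyz) - zn$position)^2))
      e <- e + cfg$w_zn * (min(d) - zn$target)^2
    }
  }
  ## closure penalty
  if (st$is_cyc && n >= 3) {
    gi <- function(res, nm) coords[which(st$cc$atom_res == res &
                                         st$cc$atom_names == nm), ]
    Cn <- gi(n, "C"); CAn <- gi(n, "CA"); N1 <- gi(1, "N"); CA1 <- gi(1, "CA")
    len <- sqrt(sum((Cn - N1)^2))
    e <- e + cfg$w_closure * ((len - cfg$ideal_cn)^2 +
      0.01 * (bond_angle(CAn, Cn, N1) - BACKBONE_GEOM$a_ca_c_n)^2 +
      0.01 * (bond_angle(Cn, N1, CA1) - BACKBONE_GEOM$a_c_n_ca)^2 +
      0.005 * wrap_angle(dihedral_cpp(CAn, Cn, N1, CA1) - 180)^2)
  }
  if (w_cst > 0 && !is.null(start_coords))
    e <- e + w_cst * mean(rowSums((coords - start_coords)^2))
  e
}

#' Locally minimize a pose in torsion space
#'
#' Optimizes backbone (phi/psi) and side-chain chi torsions of one chain
#' against the surrogate energy, keeping everything else rigid. The
#' anchor residue's coordinates are preserved exactly (the rebuilt chain
#' is rigidly re-anchored onto it). For cyclic chains a harmonic closure
#' penalty keeps the ring closed; re-validate with [closure_valid()].
#'
#' @param pose a `Pose`
#' @param movable_chain chain to move (default: last chain)
#' @param restrain_to_start add a harmonic penalty to the starting
#'   coordinates
#' @param max_iter optimizer iteration budget
#' @param cfg configuration
#' @param anchor_resno pose-wide residue index held fixed (default: first
#'   residue of the movable chain)
#' @param free which torsion kinds move: subset of c("bb", "chi")
#' @param w_cst restraint weight (per A^2) when `restrain_to_start`
#' @return minimized `Pose` with attributes `energy_initial`,
#'   `energy_final`, `converged`
#' @export
minimize_pose <- function(pose, movable_chain = NULL,
                          restrain_to_start = FALSE, max_iter = 50,
                          cfg = ax_config(), anchor_resno = NULL,
                          free = c("bb", "chi"), w_cst = 1.0) {
  if (is.null(movable_chain))
    movable_chain <- pose$chain[length(pose$chain)]
  if (is.null(anchor_resno))
    anchor_resno <- min(which(pose$chain == movable_chain))
  st <- minimize_state(pose, movable_chain, cfg, anchor_resno)
  n <- length(st$cc$codes)
  anchor_local <- match(anchor_resno, st$idx)
  free_names <- character(0)
  if ("bb" %in% free) {
    for (i in setdiff(seq_len(n), anchor_local)) {
      if (i > 1) free_names <- c(free_names, sprintf("phi_%d", i))
      if (i < n || st$is_cyc) free_names <- c(free_names, sprintf("psi_%d", i))
    }
    ## psi of residue n in an open chain only swings its carbonyl O
    if (!st$is_cyc && n > 1 && n != anchor_local)
      free_names <- c(free_names, sprintf("psi_%d", n))
  }
  if ("chi" %in% free)
    free_names <- c(free_names, grep("^chi", names(st$tv), value = TRUE))
  free_names <- unique(intersect(free_names, names(st$tv)))
  if (length(free_names) == 0) return(pose)
  start_coords <- chain_coords_at(st, st$tv)
  wc <- if (restrain_to_start) w_cst else 0
  obj <- function(par) {
    tv <- st$tv; tv[free_names] <- par
    minimize_objective(st, tv, start_coords, wc)
  }
  e0 <- obj(st$tv[free_names])
  res <- tryCatch(
    optim(st$tv[free_names], obj, method = "BFGS",
          control = list(maxit = max_iter, reltol = 1e-8)),
    error = function(e) list(par = st$tv[free_names], value = e0,
                             convergence = 52))
  if (res$value > e0) res <- list(par = st$tv[free_names], value = e0,
                                  convergence = 1)
  tv <- st$tv; tv[free_names] <- wrap_angle(res$par)
  coords <- chain_coords_at(st, tv)
  out <- pose
  for (i in seq_len(n)) {
    sel <- st$cc$atom_res == i
    m <- coords[sel, , drop = FALSE]
    rownames(m) <- st$cc$atom_names[sel]
    out$residues[[st$idx[i]]]$atoms <- m
  }
  ## anchor residue exactly preserved
  out$residues[[anchor_resno]] <- pose$residues[[anchor_resno]]
  attr(out, "energy_initial") <- e0
  attr(out, "energy_final") <- res$value
  attr(out, "converged") <- identical(res$convergence, 0L) ||
    identical(res$convergence, 0)
  if (!isTRUE(attr(out, "converged")) && res$value > e0)
    warning("minimize_pose: optimizer did not converge; best-so-far returned")
  out
}
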