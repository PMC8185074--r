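## Kinematic closure of N-to-C cyclic peptides. Non-pivot backbone
## torsions are drawn from the Ramachandran surrogate; the six torsions
## flanking three pivot residues are then solved so that the ring closes
## with ideal amide geometry. The solve is a Levenberg-Marquardt root
## find on the six pivot torsions: the chain is extended past the last
## residue by a virtual N and CA built with ideal bond geometry and a
## trans amide, and the residual is the mismatch between these virtual
## atoms and the real first-residue N and CA. At a root (residual ~ 0)
## the closure bond length, both flanking angles and the closure omega
## are ideal by construction.
##
## Rings are closed in a rotated register that puts the anchor (first
## fixed residue) at ring position 1, so the anchor's coordinates are the
## fixed frame; the solved joint becomes the bond entering the anchor.

## backbone-only internal-coordinate table (N, CA, C per residue) plus
## virtual N' and CA' closing the ring. Torsion vector: psi_1, then
## (phi_i, psi_i) for i = 2..n, then psi_n feeds the virtual N'.
compile_backbone <- function(n, root_coords) {
  g <- BACKBONE_GEOM
  nat <- 3 * n + 2
  refs <- matrix(0L, nat, 3); geom <- matrix(0, nat, 3)
  tidx <- integer(nat)
  tor_names <- c("psi_1", as.vector(t(outer(2:n, c("phi", "psi"),
                 function(i, k) sprintf("%s_%d", k, i)))))
  tmap <- setNames(seq_along(tor_names), tor_names)
  at <- function(i, k) 3L * (i - 1L) + k  # k: 1=N, 2=CA, 3=C
  for (i in 2:n) {
    ## N(i) from C(i-1), CA(i-1), N(i-1): torsion psi_{i-1}
    r <- at(i, 1L)
    refs[r, ] <- c(at(i - 1, 3L), at(i - 1, 2L), at(i - 1, 1L))
    geom[r, ] <- c(g$b_c_n, g$a_ca_c_n, 0)
    tidx[r] <- tmap[sprintf("psi_%d", i - 1)]
    ## CA(i): torsion omega_{i-1} fixed trans
    r <- at(i, 2L)
    refs[r, ] <- c(at(i, 1L), at(i - 1, 3L), at(i - 1, 2L))
    geom[r, ] <- c(g$b_n_ca, g$a_c_n_ca, 180)
    ## C(i): torsion phi_i
    r <- at(i, 3L)
    refs[r, ] <- c(at(i, 2L), at(i, 1L), at(i - 1, 3L))
    geom[r, ] <- c(g$b_ca_c, g$a_n_ca_c, 0)
    tidx[r] <- tmap[sprintf("phi_%d", i)]
  }
  ## virtual N' and CA'
  r <- 3L * n + 1L
  refs[r, ] <- c(at(n, 3L), at(n, 2L), at(n, 1L))
  geom[r, ] <- c(g$b_c_n, g$a_ca_c_n, 0)
  tidx[r] <- tmap[sprintf("psi_%d", n)]
  r <- 3L * n + 2L
  refs[r, ] <- c(3L * n + 1L, at(n, 3L), at(n, 2L))
  geom[r, ] <- c(g$b_n_ca, g$a_c_n_ca, 180)
  coords_init <- matrix(0, nat, 3)
  coords_init[1:3, ] <- root_coords
  list(refs = refs, geom = geom, tor_idx = tidx, tor_names = tor_names,
       n = n)
}

#' Define a macrocycle closure problem
#'
#' @param pose open-chain `Pose` (the peptide chain to cyclize)
#' @param fixed_residues indices whose backbone torsions are frozen; the
#'   first one is the anchor whose coordinates define the fixed frame
#' @param attempts closure attempts
#' @param chain peptide chain id
#' @return a `ClosureProblem`
#' @export
closure_problem <- function(pose, fixed_residues = integer(0),
                            attempts = 250, chain = NULL) {
  if (is.null(chain)) chain <- pose$chain[1]
  structure(list(pose = pose, fixed_residues = as.integer(fixed_residues),
                 attempts = as.integer(attempts), chain = chain),
            class = "ClosureProblem")
}

## crude reach feasibility: every inter-residue gap along the ring must
## be bridgeable by its residue count (~3.9 A per peptide unit)
closure_feasible <- function(pose, ring, fixed_ring_pos) {
  n <- length(ring)
  if (length(fixed_ring_pos) < 2) {
    ## ring must be able to reach from anchor C back around to anchor N
    return(n >= 4)
  }
  for (a in fixed_ring_pos) for (b in fixed_ring_pos) {
    if (a >= b) next
    d <- sqrt(sum((get_atom(pose, ring[a], "CA") -
                   get_atom(pose, ring[b], "CA"))^2))
    steps <- min(b - a, n - (b - a))
    if (d > steps * 3.9 + 0.5) return(FALSE)
  }
  TRUE
}

#' Close a macrocycle by kinematic loop closure
#'
#' @param problem a `ClosureProblem` (or open-chain `Pose`)
#' @param seed RNG seed (mandatory for reproducibility)
#' @param cfg configuration (`rama_cutoff`, `min_genkic_hbonds`, closure
#'   tolerances)
#' @param n_solutions stop after this many accepted solutions
#' @return list of `ClosureSolution` (possibly empty; attribute
#'   `"diagnosis"` explains emptiness), each with the closed cyclic
#'   `pose`, per-residue `torsions`, closure geometry, internal
#'   hydrogen-bond count and `rama_ok`
#' @export
close_macrocycle <- function(problem, seed = 1, cfg = ax_config(),
                             n_solutions = Inf) {
  if (inherits(problem, "Pose")) problem <- closure_problem(problem)
  pose <- problem$pose
  members <- which(pose$chain == problem$chain)
  n <- length(members)
  fixed <- problem$fixed_residues
  anchor <- if (length(fixed)) fixed[1] else members[1]
  ## ring register rotated so the anchor leads
  k <- match(anchor, members)
  ring <- members[((seq_len(n) - 1 + k - 1) %% n) + 1]
  fixed_ring_pos <- match(fixed, ring)
  if (!closure_feasible(pose, ring, fixed_ring_pos)) {
    out <- list()
    attr(out, "diagnosis") <- "infeasible: fixed anchors exceed chain reach"
    return(out)
  }
  if (n < 5) {
    out <- list()
    attr(out, "diagnosis") <- "infeasible: chain shorter than 5 residues"
    return(out)
  }
  set.seed(seed)
  codes <- pose_sequence(pose)[ring]
  root <- rbind(get_atom(pose, anchor, "N"), get_atom(pose, anchor, "CA"),
                get_atom(pose, anchor, "C"))
  cb <- compile_backbone(n, root)
  ## torsions currently on the pose, in ring register
  tt <- pose_torsions(pose)[ring, ]
  tv0 <- setNames(numeric(length(cb$tor_names)), cb$tor_names)
  for (i in seq_len(n)) {
    if (i >= 2) tv0[sprintf("phi_%d", i)] <-
        ifelse(is.na(tt$phi[i]), -60, tt$phi[i])
    tv0[sprintf("psi_%d", i)] <- ifelse(is.na(tt$psi[i]), -45, tt$psi[i])
  }
  frozen <- character(0)
  for (fp in fixed_ring_pos) {
    if (fp >= 2) frozen <- c(frozen, sprintf("phi_%d", fp))
    frozen <- c(frozen, sprintf("psi_%d", fp))
  }
  pivot_candidates <- setdiff(2:n, fixed_ring_pos)
  if (length(pivot_candidates) < 3) {
    out <- list()
    attr(out, "diagnosis") <- "fewer than 3 free residues for pivots"
    return(out)
  }
  ## prefer broad-basin (glycine-class) pivots: solved pivot torsions
  ## land anywhere, so narrow-basin residues there mostly fail the
  ## torsion filter
  broad <- pivot_candidates[vapply(pivot_candidates, function(i)
    rama_class(codes[i])$class == "gly", logical(1))]
  narrow <- setdiff(pivot_candidates, broad)
  target <- rbind(get_atom(pose, anchor, "N"), get_atom(pose, anchor, "CA"))
  coords_init <- rbind(root, matrix(0, 3 * n - 1, 3))
  tor_res <- as.integer(sub(".*_", "", cb$tor_names))
  names(tor_res) <- cb$tor_names
  solutions <- list()
  n_attempted <- 0
  for (att in seq_len(problem$attempts)) {
    if (length(solutions) >= n_solutions) break
    n_attempted <- att
    pivots <- if (length(broad) >= 3)
      sort(broad[sample.int(length(broad), 3)])
    else sort(c(broad, narrow[sample.int(length(narrow),
                                         3 - length(broad))]))
    pivot_tor <- c(sprintf("phi_%d", pivots), sprintf("psi_%d", pivots))
    sampled <- setdiff(cb$tor_names, c(frozen, pivot_tor))
    tv <- tv0
    for (nm in sampled) {
      rs <- rama_sample(codes[tor_res[nm]], 1)
      tv[nm] <- if (startsWith(nm, "phi")) rs$phi else rs$psi
    }
    tv[pivot_tor] <- wrap_angle(runif(6, -180, 180))
    pivot_ti <- match(pivot_tor, cb$tor_names)
    vrows <- (3 * n + 1):(3 * n + 2)
    resid_fn <- local({
      tv_loc <- tv
      function(par) {
        tv_loc[pivot_ti] <- par
        xyz <- ic_build_cpp(cb$refs, cb$geom, cb$tor_idx, tv_loc,
                            coords_init)
        as.numeric(xyz[vrows, ] - target)
      }
    })
    fit <- tryCatch(
      suppressWarnings(
      minpack.lm::nls.lm(par = tv[pivot_tor], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 30, ftol = 1e-14, ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(fit)) next
    res_norm <- sqrt(sum(fit$fvec^2))
    if (res_norm > 1e-6) next
    tv[pivot_tor] <- wrap_angle(fit$par)
    sol <- closure_solution(pose, ring, codes, tv, cb, pivots, cfg,
                            residual = res_norm)
    if (is.null(sol)) next
    solutions[[length(solutions) + 1]] <- sol
  }
  if (length(solutions) == 0)
    attr(solutions, "diagnosis") <- sprintf(
      "no accepted solution in %d attempts", n_attempted)
  solutions
}

## assemble a full-atom closed pose from ring-register torsions and
## apply the acceptance filters
closure_solution <- function(pose, ring, codes, tv, cb, pivots, cfg,
                             residual) {
  n <- cb$n
  anchor <- ring[1]
  tor <- cbind(phi = c(NA, tv[sprintf("phi_%d", 2:n)]),
               psi = tv[sprintf("psi_%d", seq_len(n))],
               omega = rep(180, n))
  tor[1, 1] <- -60  # placeholder; root residue phi is an outcome
  cc <- compile_chain(codes, root_coords = rbind(
    get_atom(pose, anchor, "N"), get_atom(pose, anchor, "CA"),
    get_atom(pose, anchor, "C")))
  tt_src <- pose_torsions(pose)[ring, ]
  coords <- ic_build_cpp(cc$refs, cc$geom, cc$tor_idx,
                         torsion_vector(cc, tor, tt_src$chis), cc$coords_init)
  closed <- ic_to_pose(cc, coords, chain = pose$chain[ring[1]], cyclic = TRUE)
  ## restore original residue numbering (ring register -> pose order)
  ord <- order(ring)
  closed$residues <- closed$residues[ord]
  closed$chain <- closed$chain[ord]
  ## keep the anchor bitwise identical
  closed$residues[[match(anchor, sort(ring))]] <- pose$residues[[anchor]]
  g <- closure_geometry(closed)
  tol_ok <- abs(g$length - cfg$ideal_cn) <= cfg$closure_tol_len &&
    abs(g$angle_c - BACKBONE_GEOM$a_ca_c_n) <= cfg$closure_tol_ang &&
    abs(g$angle_n - BACKBONE_GEOM$a_c_n_ca) <= cfg$closure_tol_ang
  if (!tol_ok) return(NULL)
  tt <- pose_torsions(closed)
  rama <- mapply(function(code, phi, psi) rama_score(code, phi, psi),
                 tt$code, tt$phi, tt$psi)
  rama_ok <- all(rama <= cfg$rama_cutoff, na.rm = TRUE)
  if (!rama_ok) return(NULL)
  hb <- internal_backbone_hbonds(closed)
  if (hb < cfg$min_genkic_hbonds) return(NULL)
  structure(list(pose = closed, torsions = tt[, c("resno", "phi", "psi",
                                                  "omega")],
                 pivots = ring[pivots], residual = residual,
                 closure_bond_length = g$length,
                 closure_bond_angles = c(g$angle_c, g$angle_n),
                 internal_hbonds = hb, rama_ok = rama_ok),
            class = "ClosureSolution")
}

#' Count internal backbone hydrogen bonds of a peptide
#'
#' Backbone amide N to carbonyl O pairs with N-O distance below `dmax`,
#' excluding pairs within the same or adjacent residues (ring-adjacency
#' aware for cyclic chains).
#'
#' @param pose a `Pose` (peptide only)
#' @param dmax N-O distance cutoff (A)
#' @return integer
#' @export
internal_backbone_hbonds <- function(pose, dmax = 3.5) {
  n <- pose_size(pose)
  N <- t(vapply(seq_len(n), function(i) get_atom(pose, i, "N"), numeric(3)))
  O <- t(vapply(seq_len(n), function(i) get_atom(pose, i, "O"), numeric(3)))
  cyc <- length(cyclic_chains(pose)) > 0
  count <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sep <- abs(i - j)
    if (cyc) sep <- min(sep, n - sep)
    if (sep <= 1) next
    if (sqrt(sum((N[i, ] - O[j, ])^2)) < dmax) count <- count + 1L
  }
  count
}

#' Sample an ensemble of closed, filtered macrocycle conformers
#'
#' The ensemble generator behind folding-landscape analysis: for each
#' structure, torsions are re-seeded, the ring is closed kinematically,
#' and the conformer is kept if it passes the closure tolerance, torsion
#' preference and internal hydrogen-bond filters; conformers are then
#' optionally minimized (with a closure-preserving penalty).
#'
#' @param codes residue codes of the macrocycle
#' @param n_struct conformers requested
#' @param seed RNG seed
#' @param cfg configuration (`min_final_hbonds` etc.)
#' @param minimize locally minimize each accepted conformer
#' @param max_attempts total closure-attempt budget
#' @return list of cyclic `Pose` objects (possibly shorter than
#'   `n_struct`; attribute `"stats"` reports attempts and acceptance)
#' @export
sample_closed_ensemble <- function(codes, n_struct, seed = 1,
                                   cfg = ax_config(), minimize = FALSE,
                                   max_attempts = 40 * n_struct) {
  for (code in codes)
    if (!template_exists(code)) stop("unknown residue code: ", code)
  set.seed(seed)
  base <- build_peptide(codes, c(-60, -45, 180))
  out <- list(); attempts_used <- 0
  batch_seeds <- sample.int(2^30, max_attempts)
  bi <- 0
  while (length(out) < n_struct && attempts_used < max_attempts) {
    bi <- bi + 1
    if (bi > length(batch_seeds)) break
    sols <- close_macrocycle(closure_problem(base, attempts = 5),
                             seed = batch_seeds[bi], cfg = cfg,
                             n_solutions = 1)
    attempts_used <- attempts_used + 5
    if (length(sols) == 0) next
    p <- sols[[1]]$pose
    if (minimize) {
      p <- minimize_pose(p, max_iter = 15, cfg = cfg)
      if (!closure_valid(p, cfg)) next
    }
    if (internal_backbone_hbonds(p) < cfg$min_final_hbonds) next
    out[[length(out) + 1]] <- p
  }
  attr(out, "stats") <- list(requested = n_struct, produced = length(out),
                             attempts = attempts_used)
  out
}
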