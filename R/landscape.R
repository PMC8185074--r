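## Conformational landscape (folding funnel) analysis: sample closed
## conformers of a designed macrocycle, score them, measure RMSD to the
## design, and summarize whether the designed conformation dominates the
## low-energy ensemble.

#' Cyclic-register-aware backbone RMSD between two macrocycles
#'
#' Minimum Kabsch RMSD over all rotations of the residue numbering
#' (backbone N, CA, C, O atoms).
#'
#' @param a,b cyclic `Pose` objects of equal length
#' @return RMSD in A
#' @export
cyclic_rmsd <- function(a, b) {
  n <- pose_size(a)
  if (pose_size(b) != n) stop("poses differ in length")
  bb <- function(p, ord) do.call(rbind, lapply(ord, function(i)
    p$residues[[i]]$atoms[c("N", "CA", "C", "O"), , drop = FALSE]))
  xb <- bb(b, seq_len(n))
  best <- Inf
  for (shift in 0:(n - 1)) {
    ord <- ((seq_len(n) - 1 + shift) %% n) + 1
    ## registers must match residue types to be comparable
    if (!identical(pose_sequence(a)[ord], pose_sequence(b))) next
    r <- superpose(bb(a, ord), xb)$rmsd
    if (r < best) best <- r
  }
  if (!is.finite(best))  # no type-compatible register: use register 0
    best <- superpose(bb(a, seq_len(n)), xb)$rmsd
  best
}

#' Build the energy landscape of a macrocycle sequence
#'
#' Samples closed, filtered conformers (see [sample_closed_ensemble()]),
#' scores each with the surrogate energy, and measures cyclic-register-
#' aware backbone RMSD to the designed conformation.
#'
#' @param sequence residue codes (must match the design pose)
#' @param design_pose the designed cyclic conformation
#' @param n_struct conformers requested
#' @param seed RNG seed
#' @param cfg configuration
#' @param include_design also score the design pose itself (one point at
#'   RMSD 0)
#' @param minimize minimize each conformer
#' @param max_attempts closure-attempt budget
#' @return `LandscapeEnsemble`: data.frame (energy, rmsd) with
#'   attributes `design_pose`, `stats`
#' @export
build_landscape <- function(sequence, design_pose, n_struct, seed = 1,
                            cfg = ax_config(), include_design = FALSE,
                            minimize = FALSE, max_attempts = 60 * n_struct) {
  if (length(sequence) != pose_size(design_pose))
    stop("sequence length does not match design pose")
  ens <- sample_closed_ensemble(sequence, n_struct, seed = seed, cfg = cfg,
                                minimize = minimize,
                                max_attempts = max_attempts)
  pts <- data.frame(energy = numeric(0), rmsd = numeric(0))
  for (p in ens) {
    pts <- rbind(pts, data.frame(
      energy = as.numeric(total_energy(p, cfg)),
      rmsd = cyclic_rmsd(p, design_pose)))
  }
  if (include_design)
    pts <- rbind(data.frame(
      energy = as.numeric(total_energy(design_pose, cfg)), rmsd = 0), pts)
  structure(pts, class = c("LandscapeEnsemble", class(pts)),
            design_pose = design_pose, stats = attr(ens, "stats"))
}

#' Funnel statistics of a landscape ensemble
#'
#' `pnear = sum_i exp(-r_i^2/lambda^2) exp(-E_i/kT) / sum_i exp(-E_i/kT)`
#' plus the energy gap between the best conformer beyond `near_cutoff`
#' and the best within it (positive gap = funnel centered on the
#' design), and the RMSD of the energy minimum.
#'
#' @param ensemble a `LandscapeEnsemble` (or data.frame with energy,
#'   rmsd)
#' @param lambda Pnear distance scale (A)
#' @param kT Pnear temperature (surrogate energy units)
#' @param near_cutoff near/far RMSD boundary (A)
#' @return `FunnelStats`: pnear, energy_gap, min_energy_rmsd, n
#' @export
funnel_stats <- function(ensemble, lambda = 1.5, kT = 1, near_cutoff = 1.5) {
  if (nrow(ensemble) < 2) stop("need at least 2 landscape points")
  e <- ensemble$energy - min(ensemble$energy)
  w <- exp(-e / kT)
  pnear <- sum(exp(-ensemble$rmsd^2 / lambda^2) * w) / sum(w)
  near <- ensemble$rmsd <= near_cutoff
  ## when one side of the cutoff is unsampled, fall back to a bound:
  ## no far points -> the gap is at least spread of sampled energies;
  ## no near points -> at most minus that spread
  gap <- if (any(near) && any(!near))
    min(ensemble$energy[!near]) - min(ensemble$energy[near])
  else if (all(near)) max(ensemble$energy) - min(ensemble$energy)
  else -(max(ensemble$energy) - min(ensemble$energy))
  structure(list(pnear = pnear, energy_gap = gap,
                 min_energy_rmsd = ensemble$rmsd[which.min(ensemble$energy)],
                 n = nrow(ensemble)),
            class = "FunnelStats")
}

#' @export
print.FunnelStats <- function(x, ...) {
  cat(sprintf("FunnelStats: pnear=%.3f gap=%s min-E rmsd=%.2f A (n=%d)\n",
              x$pnear,
              ifelse(is.na(x$energy_gap), "NA",
                     sprintf("%.2f", x$energy_gap)),
              x$min_energy_rmsd, x$n))
  invisible(x)
}

#' Select designs by folding funnel quality
#'
#' Keeps candidates whose ensembles indicate the designed conformation
#' dominates (pnear and energy gap above thresholds). When an ensemble
#' failed to sample near the design at all (no near points, gap NA), the
#' optional interface fallback keeps candidates on interface metrics
#' alone, mirroring practice when folding analysis is uninformative.
#'
#' @param candidates list of `list(record=, funnel=)` pairs
#' @param policy list: pnear_min, gap_min, fallback_interface (logical),
#'   ddg_max used by the fallback
#' @return list of selected `DesignRecord`; attribute `"reasons"`
#' @export
select_by_funnel <- function(candidates,
                             policy = list(pnear_min = 0.5, gap_min = 0,
                                           fallback_interface = FALSE,
                                           ddg_max = -10)) {
  if (length(candidates) == 0) stop("no candidates")
  keep <- list(); reasons <- character(0)
  for (cand in candidates) {
    fs <- cand$funnel
    if (!is.na(fs$energy_gap) && fs$pnear >= policy$pnear_min &&
        fs$energy_gap >= policy$gap_min) {
      keep[[length(keep) + 1]] <- cand$record
      reasons <- c(reasons, "funnel")
    } else if (isTRUE(policy$fallback_interface) && is.na(fs$energy_gap) &&
               cand$record$report$ddg < policy$ddg_max) {
      keep[[length(keep) + 1]] <- cand$record
      reasons <- c(reasons, "interface-fallback")
    } else {
      reasons <- c(reasons, "rejected")
    }
  }
  attr(keep, "reasons") <- reasons
  keep
}
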