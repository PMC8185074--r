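## Method 1: rigid superposition docking of pre-built macrocycle
## scaffolds onto the pocket-embedded anchor. For every scaffold residue
## (every cyclic register), the residue's {C, N, O, CA, CB} atoms are
## least-squares superposed onto the anchor's, the whole scaffold is
## carried along, the aligned residue is replaced by the anchor (side
## chain grafted with the anchor's chi angles), and the pose is screened
## for backbone clashes against the receptor.

#' Dock a scaffold macrocycle onto the pocket anchor
#'
#' @param scaffold cyclic `Pose` (a macrocycle)
#' @param target_with_anchor complex `Pose` holding the receptor and the
#'   anchor residue (e.g. from [seed_anchor_in_pocket()])
#' @param anchor_index pose-wide residue index of the anchor in
#'   `target_with_anchor` (default: first residue of the last chain)
#' @param cfg configuration
#' @return list of `DockPose`: one per scaffold register, each with the
#'   docked complex, alignment RMSD, clash count and `accepted = NA`
#'   (set by [screen_and_relax()])
#' @export
dock_on_anchor <- function(scaffold, target_with_anchor, anchor_index = NULL,
                           cfg = ax_config()) {
  if (length(cyclic_chains(scaffold)) == 0)
    stop("scaffold must be cyclic")
  if (is.null(anchor_index)) {
    pep_chain <- target_with_anchor$chain[length(target_with_anchor$chain)]
    anchor_index <- min(which(target_with_anchor$chain == pep_chain))
  }
  anchor_res <- target_with_anchor$residues[[anchor_index]]
  anchor_tpl <- get_template(anchor_res$code)
  align_names <- c("C", "N", "O", "CA", "CB")
  if (!all(align_names %in% rownames(anchor_res$atoms)))
    stop("anchor lacks required atoms: ",
         paste(setdiff(align_names, rownames(anchor_res$atoms)),
               collapse = ", "))
  anchor_xyz <- anchor_res$atoms[align_names, , drop = FALSE]
  anchor_chis <- pose_torsions(target_with_anchor)$chis[[anchor_index]]
  receptor <- pose_chain_subset(
    target_with_anchor,
    setdiff(unique(target_with_anchor$chain),
            target_with_anchor$chain[anchor_index]))
  n <- pose_size(scaffold)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    res <- scaffold$residues[[r]]
    have <- intersect(align_names, rownames(res$atoms))
    gly_mode <- !"CB" %in% have   # glycine register: 4-atom alignment
    mob <- res$atoms[have, , drop = FALSE]
    tr <- superpose(mob, anchor_xyz[have, , drop = FALSE])
    docked <- scaffold
    for (i in seq_len(n))
      docked$residues[[i]]$atoms <-
        apply_transform(docked$residues[[i]]$atoms, tr)
    ## graft the anchor into the aligned register
    bb <- docked$residues[[r]]$atoms[
      intersect(c("N", "CA", "C", "O"), rownames(docked$residues[[r]]$atoms)),
      , drop = FALSE]
    grafted <- build_side_chain(list(code = anchor_res$code, atoms = bb),
                                anchor_chis)
    docked$residues[[r]] <- grafted
    docked$chain <- rep("P", n)
    complex_pose <- pose_merge(receptor, docked)
    cl <- backbone_clashes(complex_pose, "P", cfg$clash_overlap)
    out[[r]] <- structure(list(
      scaffold_id = attr(scaffold, "id"),
      aligned_residue_index = r,
      transform = tr, align_rmsd = tr$rmsd, gly_alignment = gly_mode,
      complex = complex_pose, clash_count = cl, accepted = NA),
      class = "DockPose")
  }
  out
}

#' Clashes between a peptide's backbone and the rest of the complex
#'
#' Counts receptor heavy atoms overlapping the peptide's N/CA/C/O/CB
#' atoms (vdW radii minus `overlap`); the screening statistic of
#' superposition docking.
#'
#' @param complex_pose a `Pose`
#' @param peptide_chain peptide chain id
#' @param overlap allowed overlap (A)
#' @return integer
#' @export
backbone_clashes <- function(complex_pose, peptide_chain = "P",
                             overlap = 0.5) {
  df <- pose_atoms(complex_pose, include_het = FALSE)
  bb <- df[df$chain == peptide_chain &
           df$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  rec <- df[df$chain != peptide_chain, , drop = FALSE]
  if (nrow(bb) == 0 || nrow(rec) == 0) return(0L)
  cnt <- 0L
  rxyz <- coords_matrix(rec)
  for (i in seq_len(nrow(bb))) {
    d <- sqrt(colSums((t(rxyz) - as.numeric(bb[i, c("x", "y", "z")]))^2))
    cnt <- cnt + sum(d < bb$radius[i] + rec$radius - overlap)
  }
  as.integer(cnt)
}

#' Screen docked poses for clashes and optionally relax the survivors
#'
#' @param dockposes list of `DockPose` from [dock_on_anchor()]
#' @param max_clashes accepted poses may have at most this many
#'   backbone-receptor clashes
#' @param relax minimize accepted poses (restrained to start)
#' @param cfg configuration
#' @return accepted `DockPose` list, sorted by (clash_count, energy)
#' @export
screen_and_relax <- function(dockposes, max_clashes = 3, relax = FALSE,
                             cfg = ax_config()) {
  if (length(dockposes) == 0) return(list())
  kept <- list()
  for (dp in dockposes) {
    dp$accepted <- dp$clash_count <= max_clashes
    if (!dp$accepted) next
    if (relax) {
      e0 <- as.numeric(total_energy(dp$complex, cfg))
      relaxed <- minimize_pose(dp$complex, movable_chain = "P",
                               restrain_to_start = TRUE, max_iter = 30,
                               cfg = cfg)
      e1 <- as.numeric(total_energy(relaxed, cfg))
      if (e1 <= e0) { dp$complex <- relaxed; dp$energy <- e1 }
      else dp$energy <- e0
      dp$clash_count <- backbone_clashes(dp$complex, "P", cfg$clash_overlap)
    } else {
      dp$energy <- as.numeric(total_energy(dp$complex, cfg))
    }
    kept[[length(kept) + 1]] <- dp
  }
  if (length(kept) == 0) return(list())
  ord <- order(vapply(kept, `[[`, numeric(1), "clash_count"),
               vapply(kept, `[[`, numeric(1), "energy"))
  kept[ord]
}
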