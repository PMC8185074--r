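## Anchor extension and sequence design. The anchor residue is never
## touched: its template and coordinates are preserved bitwise across
## extension, scanning, closure and design. Scanned/designed positions
## obey the backbone chirality rule (negative phi -> L template,
## positive phi -> D template).

#' Extend a peptide chain outward from the pocket anchor
#'
#' Grows `n_after` residues C-terminal and `n_before` residues
#' N-terminal of the anchor with ideal geometry, re-sampling backbone
#' torsions from the Ramachandran surrogate until the new backbone does
#' not clash irreparably with the receptor.
#'
#' @param target_with_anchor complex `Pose` (receptor + anchor chain)
#' @param n_before,n_after residues to add on each side
#' @param codes template codes for the new residues (recycled), order:
#'   N-terminal additions outward-first, then C-terminal additions
#' @param seed RNG seed for torsion re-sampling
#' @param max_tries resampling attempts before giving up
#' @param clash_budget tolerated backbone-receptor clashes
#' @param cfg configuration
#' @return complex `Pose`; attribute `"anchor_index"` gives the anchor's
#'   new pose-wide index
#' @export
extend_anchor <- function(target_with_anchor, n_before = 0, n_after = 0,
                          codes = "GLY", seed = 1, max_tries = 50,
                          clash_budget = 0, cfg = ax_config()) {
  pose <- target_with_anchor
  pep_chain <- pose$chain[length(pose$chain)]
  pep_idx <- which(pose$chain == pep_chain)
  total <- n_before + n_after + length(pep_idx)
  if (total > 9)
    stop("extension exceeds 9 residues total")
  codes <- rep_len(codes, n_before + n_after)
  codes_before <- rev(utils::head(codes, n_before))  # inward order
  codes_after <- utils::tail(codes, n_after)
  anchor_global <- pep_idx[1]
  anchor_res <- pose$residues[[anchor_global]]
  set.seed(seed)
  rec_chains <- setdiff(unique(pose$chain), pep_chain)
  for (try in seq_len(max_tries)) {
    pep <- pose_chain_subset(pose, pep_chain, keep_het = FALSE)
    ## forward growth: rebuild [existing chain..., new residues] rooted
    ## on the anchor's actual backbone
    if (n_after > 0) {
      old_codes <- pose_sequence(pep)
      all_codes <- c(old_codes, codes_after)
      tt <- pose_torsions(pep)
      tor <- matrix(c(-60, -45, 180), length(all_codes), 3, byrow = TRUE)
      for (i in seq_along(old_codes)) {
        if (!is.na(tt$phi[i])) tor[i, 1] <- tt$phi[i]
        if (!is.na(tt$psi[i])) tor[i, 2] <- tt$psi[i]
        if (!is.na(tt$omega[i])) tor[i, 3] <- tt$omega[i]
      }
      for (k in seq_along(codes_after)) {
        rs <- rama_sample(codes_after[k], 1)
        tor[length(old_codes) + k, ] <- c(rs$phi, rs$psi, 180)
      }
      ## psi of the old last residue now carries a real amide
      tor[length(old_codes), 2] <- rama_sample(old_codes[length(old_codes)],
                                               1)$psi
      cc <- compile_chain(all_codes, root_coords = rbind(
        get_atom(pep, 1, "N"), get_atom(pep, 1, "CA"),
        get_atom(pep, 1, "C")))
      coords <- ic_build_cpp(cc$refs, cc$geom, cc$tor_idx,
                             torsion_vector(cc, tor, tt$chis), cc$coords_init)
      pep <- ic_to_pose(cc, coords, chain = pep_chain)
      pep$residues[[1]] <- anchor_res  # bitwise anchor
    }
    if (n_before > 0) {
      for (k in seq_along(codes_before)) {
        first_tt <- pose_torsions(pep)
        phi_first <- rama_sample(pose_sequence(pep)[1], 1)$phi
        rs <- rama_sample(codes_before[k], 1)
        pep <- grow_backward(pep, codes_before[k], phi_first, rs$psi,
                             omega_new = 180)
      }
    }
    candidate <- pose_merge(
      pose_chain_subset(pose, rec_chains, keep_het = TRUE), pep)
    if (backbone_clashes(candidate, pep_chain, cfg$clash_overlap) <=
        clash_budget) {
      attr(candidate, "anchor_index") <-
        sum(candidate$chain != pep_chain) + n_before + 1
      return(candidate)
    }
  }
  stop("extension collides irreparably with the receptor backbone")
}

## choose the L or D variant of `code` according to the chirality rule
apply_chirality_rule <- function(code, phi) {
  tpl <- get_template(code)
  if (tpl$chirality == "achiral") return(code)
  want <- chirality_for_phi(phi)
  if (tpl$chirality == want) code else mirror_code(code)
}

## best rotamer of `code` at a residue position, by complex energy;
## returns list(pose, energy) or NULL if all rotamers clash badly
best_rotamer_at <- function(pose, resno, code, cfg) {
  tpl <- get_template(code)
  res <- pose$residues[[resno]]
  res$code <- code
  best <- NULL; best_e <- Inf
  rot <- tpl$rotamers
  for (r in seq_len(nrow(rot))) {
    cand <- pose
    cand$residues[[resno]] <- build_side_chain(
      list(code = code, atoms = res$atoms[intersect(c("N", "CA", "C", "O"),
                                                    rownames(res$atoms)), ,
                                          drop = FALSE]),
      if (ncol(rot)) rot[r, ] else numeric(0))
    e <- as.numeric(total_energy(cand, cfg))
    if (e < best_e) { best_e <- e; best <- cand }
  }
  list(pose = best, energy = best_e)
}

#' Grid scan of an anchor-flanking residue
#'
#' Samples the neighbor's backbone on a square (phi, psi) grid
#' (half-open bins, default 30 degrees -> 144 bins) and, per bin, tries
#' each candidate residue type (L or D variant chosen by the chirality
#' rule), places the best rotamer, and records the interface metrics.
#' Clashing cells are flagged infeasible, never dropped: the matrix is
#' complete.
#'
#' @param pose complex `Pose` with the anchor and one free neighbor
#' @param anchor_index pose-wide anchor residue index
#' @param side "before" or "after" (which neighbor is scanned)
#' @param width grid width in degrees (must divide 360)
#' @param codes candidate residue codes (L codes; D chosen by rule)
#' @param cfg configuration
#' @param sc also compute shape complementarity per cell (slow)
#' @param max_backbone_clashes feasibility threshold
#' @return data.frame of `ScanCell` rows: phi_bin, psi_bin, phi, psi,
#'   base_code, code, chirality, feasible, ddg, sc
#' @export
grid_scan_neighbors <- function(pose, anchor_index, side = c("after", "before"),
                                width = 30, codes = canonical_codes(),
                                cfg = ax_config(), sc = FALSE,
                                max_backbone_clashes = 3) {
  side <- match.arg(side)
  centers <- torsion_bin_centers(width)
  neighbor <- anchor_index + if (side == "after") 1L else -1L
  pep_chain <- pose$chain[anchor_index]
  if (neighbor < 1 || neighbor > pose_size(pose) ||
      pose$chain[neighbor] != pep_chain)
    stop("no free neighbor residue on side '", side, "'")
  rows <- list()
  for (b in seq_len(nrow(centers))) {
    phi <- centers$phi[b]; psi <- centers$psi[b]
    shaped <- scan_set_neighbor(pose, anchor_index, neighbor, side, phi, psi)
    feasible <- backbone_clashes(shaped, pep_chain, cfg$clash_overlap) <=
      max_backbone_clashes
    for (code in codes) {
      use_code <- apply_chirality_rule(code, phi)
      if (!feasible) {
        rows[[length(rows) + 1]] <- data.frame(
          phi_bin = centers$phi_bin[b], psi_bin = centers$psi_bin[b],
          phi = phi, psi = psi, base_code = code, code = use_code,
          chirality = get_template(use_code)$chirality,
          feasible = FALSE, ddg = NA_real_, sc = NA_real_)
        next
      }
      br <- best_rotamer_at(shaped, neighbor, use_code, cfg)
      dd <- ddg_bind(br$pose, pep_chain, repack = FALSE, cfg = cfg)
      scv <- if (sc) tryCatch(
        shape_complementarity(br$pose,
                              setdiff(unique(pose$chain), pep_chain),
                              pep_chain, cfg),
        error = function(e) NA_real_) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        phi_bin = centers$phi_bin[b], psi_bin = centers$psi_bin[b],
        phi = phi, psi = psi, base_code = code, code = use_code,
        chirality = get_template(use_code)$chirality,
        feasible = TRUE, ddg = dd, sc = scv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## rebuild the scanned neighbor at given backbone torsions, keeping the
## anchor bitwise fixed
scan_set_neighbor <- function(pose, anchor_index, neighbor, side, phi, psi) {
  pep_chain <- pose$chain[anchor_index]
  rec_chains <- setdiff(unique(pose$chain), pep_chain)
  pep <- pose_chain_subset(pose, pep_chain, keep_het = FALSE)
  a_local <- anchor_index - sum(pose$chain %in% rec_chains)
  nb_local <- neighbor - sum(pose$chain %in% rec_chains)
  if (side == "after") {
    pep2 <- set_torsion(pep, nb_local, "phi", phi)
    pep2 <- set_torsion(pep2, nb_local, "psi", psi)
  } else {
    ## neighbor precedes the anchor: regrow it backward so the anchor
    ## (and everything after) never moves
    tt <- pose_torsions(pep)
    stub <- pep
    stub$residues <- stub$residues[-seq_len(nb_local)]
    stub$chain <- stub$chain[-seq_len(nb_local)]
    phi_first <- if (!is.na(tt$phi[nb_local + 1])) tt$phi[nb_local + 1] else -60
    pep2 <- grow_backward(stub, pep$residues[[nb_local]]$code,
                          phi_first, psi)
    ## phi of the regrown neighbor has no structural effect yet (no
    ## residue precedes it); it is carried for rama/chirality
  }
  pep2$residues[[a_local]] <- pose$residues[[anchor_index]]
  pose_merge(pose_chain_subset(pose, rec_chains, keep_het = TRUE), pep2)
}

#' Stochastic scan of an anchor-flanking residue
#'
#' Continuous Ramachandran-biased sampling of the neighbor's backbone
#' followed by side-chain placement; results are binned on the standard
#' grid keeping the best ddG per (bin, code).
#'
#' @param pose complex `Pose` with anchor and one free neighbor
#' @param anchor_index pose-wide anchor index
#' @param n_samples number of backbone samples
#' @param seed RNG seed
#' @param side "before" or "after"
#' @param width binning width (deg)
#' @param codes candidate codes
#' @param cfg configuration
#' @return data.frame of populated `ScanCell` rows (per-bin best)
#' @export
stochastic_scan_neighbors <- function(pose, anchor_index, n_samples,
                                      seed = 1, side = "after", width = 30,
                                      codes = c("ALA"), cfg = ax_config()) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(seed)
  neighbor <- anchor_index + if (side == "after") 1L else -1L
  pep_chain <- pose$chain[anchor_index]
  best <- list()
  for (s in seq_len(n_samples)) {
    mirror <- runif(1) < 0.5
    rs <- rama_sample("ALA", 1)  # generic basin; mirrored half the time
    phi <- if (mirror) -rs$phi else rs$phi
    psi <- if (mirror) -rs$psi else rs$psi
    shaped <- scan_set_neighbor(pose, anchor_index, neighbor, side, phi, psi)
    if (backbone_clashes(shaped, pep_chain, cfg$clash_overlap) > 3) next
    bin <- bin_torsions(phi, psi, width)
    for (code in codes) {
      use_code <- apply_chirality_rule(code, phi)
      br <- best_rotamer_at(shaped, neighbor, use_code, cfg)
      dd <- ddg_bind(br$pose, pep_chain, repack = FALSE, cfg = cfg)
      key <- paste(bin$phi_bin, bin$psi_bin, code)
      if (is.null(best[[key]]) || dd < best[[key]]$ddg)
        best[[key]] <- data.frame(
          phi_bin = bin$phi_bin, psi_bin = bin$psi_bin,
          phi = phi, psi = psi, base_code = code, code = use_code,
          chirality = get_template(use_code)$chirality,
          feasible = TRUE, ddg = dd, sc = NA_real_)
    }
  }
  out <- do.call(rbind, unname(best))
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Monte Carlo sequence design of a peptide-receptor complex
#'
#' Simulated-annealing search over residue identity (chirality rule
#' applied per position) and rotamer at the designable positions,
#' punctuated by side-chain torsion minimization. Anchor and fixed
#' positions never change identity or coordinates; with a water motif,
#' the motif residues' backbone is additionally asserted frozen and the
#' structural waters take part in scoring throughout.
#'
#' @param complex_pose receptor + peptide complex
#' @param designable pose-wide indices to design
#' @param fixed pose-wide indices that must not change (anchor included)
#' @param iterations Monte Carlo steps
#' @param seed RNG seed
#' @param water_motif optional list(residues=, torsions=) naming frozen
#'   motif residues (anchor and its predecessor) and their backbone
#'   torsions
#' @param codes design alphabet (L codes; D variant chosen by rule)
#' @param cfg configuration
#' @param sc compute shape complementarity in the final report
#' @return a `DesignRecord`: sequence, pose, report, method, provenance
#' @export
design_sequence <- function(complex_pose, designable, fixed,
                            iterations = 150, seed = 1, water_motif = NULL,
                            codes = canonical_codes(), cfg = ax_config(),
                            sc = TRUE) {
  if (length(intersect(designable, fixed)))
    stop("designable and fixed sets overlap")
  pep_chain <- complex_pose$chain[if (length(designable)) designable[1]
                                  else fixed[1]]
  if (length(designable) == 0) {
    warning("no designable positions; returning identity design")
    rec <- make_design_record(complex_pose, pep_chain, NA, seed, cfg, sc)
    return(rec)
  }
  set.seed(seed)
  tt0 <- pose_torsions(complex_pose)
  pose <- complex_pose
  e_cur <- as.numeric(total_energy(pose, cfg))
  best_pose <- pose; e_best <- e_cur
  temps <- cfg$mc_t_start * (cfg$mc_t_end / cfg$mc_t_start)^
    (seq_len(iterations) / iterations)
  for (it in seq_len(iterations)) {
    i <- designable[sample.int(length(designable), 1)]
    phi_i <- tt0$phi[i]
    if (is.na(phi_i)) phi_i <- -60
    mutate <- runif(1) < 0.5
    cand <- pose
    if (mutate) {
      ## identity move with rotamer trials: the new residue type enters
      ## at its best enumerated rotamer
      code <- apply_chirality_rule(codes[sample.int(length(codes), 1)], phi_i)
      br <- best_rotamer_at(pose, i, code, cfg)
      cand <- br$pose
      e_new <- br$energy
      if (e_new <= e_cur || runif(1) < exp(-(e_new - e_cur) / temps[it])) {
        pose <- cand; e_cur <- e_new
        if (e_cur < e_best) { best_pose <- pose; e_best <- e_cur }
      }
      next
    } else {
      code <- pose$residues[[i]]$code
      tpl <- get_template(code)
      rot <- tpl$rotamers
      if (ncol(rot) == 0) next
      chis <- rot[sample.int(nrow(rot), 1), ] +
        rnorm(ncol(rot), 0, 10)
    }
    bb <- pose$residues[[i]]$atoms[
      intersect(c("N", "CA", "C", "O"), rownames(pose$residues[[i]]$atoms)),
      , drop = FALSE]
    cand$residues[[i]] <- build_side_chain(list(code = code, atoms = bb),
                                           chis)
    e_new <- as.numeric(total_energy(cand, cfg))
    if (e_new <= e_cur || runif(1) < exp(-(e_new - e_cur) / temps[it])) {
      pose <- cand; e_cur <- e_new
      if (e_cur < e_best) { best_pose <- pose; e_best <- e_cur }
    }
  }
  rec <- make_design_record(best_pose, pep_chain, NA, seed, cfg, sc)
  rec$energy <- e_best
  rec
}

make_design_record <- function(pose, pep_chain, method, seed, cfg,
                               sc = TRUE) {
  structure(list(
    sequence = pose_sequence(pose, pep_chain),
    pose = pose,
    report = interface_report(pose, pep_chain, cfg, sc = sc),
    method = method,
    energy = as.numeric(total_energy(pose, cfg)),
    provenance = list(seed = seed,
                      config_hash = sum(unlist(Filter(is.numeric, cfg))))),
    class = "DesignRecord")
}

#' @export
print.DesignRecord <- function(x, ...) {
  cat(sprintf("DesignRecord [%s]: %s | ddg=%.2f sc=%s\n",
              ifelse(is.na(x$method), "-", x$method),
              paste(x$sequence, collapse = "-"),
              x$report$ddg,
              ifelse(is.na(x$report$sc), "NA",
                     sprintf("%.3f", x$report$sc))))
  invisible(x)
}

#' Tabulate design records
#' @param records list of `DesignRecord`
#' @return data.frame with sequence, method, energy and interface metrics
#' @export
records_table <- function(records) {
  do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(id = i, sequence = paste(r$sequence, collapse = " "),
               method = r$method, energy = r$energy,
               ddg = r$report$ddg, sc = r$report$sc,
               contacts = r$report$contacts,
               buried_unsats = r$report$buried_unsats,
               clashes = r$report$clashes)
  }))
}

#' Filter designs by hard cut-offs and per-metric top fraction
#'
#' Hard cut-offs first (shape complementarity above `sc_min`, ddG below
#' `ddg_max`), then the intersection of the per-metric top fractions
#' (total score and ddG: lowest; shape complementarity and contacts:
#' highest). Output is stably ordered by ddG.
#'
#' @param records list of `DesignRecord`
#' @param sc_min hard shape-complementarity cutoff (exclusive)
#' @param ddg_max hard ddG cutoff (exclusive)
#' @param top_frac per-metric top fraction for the intersection
#' @return filtered list of `DesignRecord`
#' @export
filter_designs <- function(records, sc_min = 0.65, ddg_max = -10,
                           top_frac = 0.01) {
  if (length(records) == 0) stop("records must be non-empty")
  tab <- records_table(records)
  hard <- which(!is.na(tab$sc) & tab$sc > sc_min &
                !is.na(tab$ddg) & tab$ddg < ddg_max)
  if (length(hard) == 0) return(list())
  sub <- tab[hard, ]
  k <- max(1L, ceiling(top_frac * nrow(sub)))
  top_low <- function(v) rank(v, ties.method = "min") <= k
  top_high <- function(v) rank(-v, ties.method = "min") <= k
  keep <- top_low(sub$energy) & top_high(sub$sc) & top_low(sub$ddg) &
    top_high(sub$contacts)
  chosen <- sub$id[keep]
  chosen <- chosen[order(sub$ddg[keep])]
  records[chosen]
}
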