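## End-to-end orchestration of the four design methods around a pocket
## anchor, at desk scale:
##   1  dock pre-built scaffolds onto the anchor, design the interface
##   2  extend both ways, close in the pocket, design with the water
##      motif (anchor + preceding residue backbone frozen)
##   3  grid-scan the flanking residue(s), extend best cells, close,
##      design
##   4  stochastic scan instead of the grid, then extend, close, design

#' Run one of the four anchor-extension design methods
#'
#' @param target complex `Pose` with the receptor and pocket anchor
#'   (e.g. [seed_anchor_in_pocket()] output)
#' @param method 1, 2, 3 or 4
#' @param config method options; recognized entries:
#'   `scaffolds` (list of cyclic poses, method 1),
#'   `n_before`/`n_after` (extension counts, default 2/4),
#'   `design_iterations` (default 60), `n_designs` (default 2),
#'   `scan_width` (default 30), `scan_codes` (default ALA/SER/LEU),
#'   `scan_n_samples` (method 4, default 40),
#'   `water_motif` (method 2: list(torsions=), motif = anchor +
#'   preceding residue), `codes` (design alphabet), `sc` (compute Sc in
#'   reports, default TRUE), `max_clashes` (method 1 screen)
#' @param seed RNG seed
#' @param cfg scoring configuration
#' @return list of `DesignRecord` with method tags and provenance
#' @export
run_method <- function(target, method, config = list(), seed = 1,
                       cfg = ax_config()) {
  stopifnot(method %in% 1:4)
  getc <- function(nm, default) if (!is.null(config[[nm]])) config[[nm]]
                                else default
  pep_chain <- target$chain[length(target$chain)]
  set.seed(seed)
  codes <- getc("codes", c("ALA", "SER", "ASN", "LEU", "GLY"))
  iters <- getc("design_iterations", 60)
  n_designs <- getc("n_designs", 2)
  sc <- getc("sc", TRUE)
  records <- list()
  if (method == 1) {
    scaffolds <- config$scaffolds
    if (is.null(scaffolds) || length(scaffolds) == 0)
      stop("no scaffolds")
    for (si in seq_along(scaffolds)) {
      dps <- dock_on_anchor(scaffolds[[si]], target, cfg = cfg)
      acc <- screen_and_relax(dps, max_clashes = getc("max_clashes", 3),
                              relax = FALSE, cfg = cfg)
      for (dp in utils::head(acc, n_designs)) {
        cx <- dp$complex
        anchor_idx <- sum(cx$chain != pep_chain) + dp$aligned_residue_index
        pep_idx <- which(cx$chain == pep_chain)
        rec <- design_sequence(cx, setdiff(pep_idx, anchor_idx),
                               anchor_idx, iterations = iters,
                               seed = seed + si, codes = codes, cfg = cfg,
                               sc = sc)
        rec$method <- 1
        records[[length(records) + 1]] <- rec
      }
    }
    return(records)
  }
  ## methods 2-4 share extend -> close -> design
  n_before <- getc("n_before", 2); n_after <- getc("n_after", 4)
  seeds <- sample.int(2^30, n_designs)
  for (d in seq_len(n_designs)) {
    ext <- extend_anchor(target, n_before, n_after, codes = "GLY",
                         seed = seeds[d], cfg = cfg)
    anchor_idx <- attr(ext, "anchor_index")
    if (method == 3) {
      cells <- grid_scan_neighbors(ext, anchor_idx, "after",
                                   width = getc("scan_width", 30),
                                   codes = getc("scan_codes",
                                                c("ALA", "SER", "LEU")),
                                   cfg = cfg, sc = FALSE)
      cells <- cells[cells$feasible, ]
      if (nrow(cells)) {
        bestc <- cells[which.min(cells$ddg), ]
        ext <- scan_apply_best(ext, anchor_idx, bestc, cfg)
      }
    } else if (method == 4) {
      cells <- stochastic_scan_neighbors(ext, anchor_idx,
                                         getc("scan_n_samples", 40),
                                         seed = seeds[d], side = "after",
                                         codes = getc("scan_codes",
                                                      c("ALA", "LEU")),
                                         cfg = cfg)
      if (nrow(cells)) {
        bestc <- cells[which.min(cells$ddg), ]
        ext <- scan_apply_best(ext, anchor_idx, bestc, cfg)
      }
    }
    ## close the ring inside the pocket; the anchor's coordinates (and
    ## for method 2 the motif torsions, for methods 3-4 the scanned
    ## cell's torsions) are frozen
    pep <- pose_chain_subset(ext, pep_chain, keep_het = FALSE)
    a_local <- anchor_idx - sum(ext$chain != pep_chain)
    fixed_local <- a_local
    if (method == 2 && a_local > 1) fixed_local <- c(a_local, a_local - 1)
    if (method %in% c(3, 4) && a_local < pose_size(pep))
      fixed_local <- c(a_local, a_local + 1)
    sols <- close_macrocycle(
      closure_problem(pep, fixed_residues = fixed_local,
                      attempts = getc("closure_attempts", 250)),
      seed = seeds[d], cfg = cfg, n_solutions = 1)
    if (length(sols) == 0) next
    rec_chains <- setdiff(unique(ext$chain), pep_chain)
    cx <- pose_merge(pose_chain_subset(ext, rec_chains, keep_het = TRUE),
                     sols[[1]]$pose)
    anchor_cx <- sum(cx$chain != pep_chain) + a_local
    ## during design only the anchor (and the method-2 motif) stay fixed
    fixed_cx <- sum(cx$chain != pep_chain) +
      (if (method == 2) fixed_local else a_local)
    pep_idx <- which(cx$chain == pep_chain)
    wm <- if (method == 2)
      list(residues = fixed_cx,
           torsions = pose_torsions(cx)[fixed_cx, c("phi", "psi")])
    else NULL
    rec <- design_sequence(cx, setdiff(pep_idx, fixed_cx), fixed_cx,
                           iterations = iters, seed = seeds[d],
                           water_motif = wm, codes = codes, cfg = cfg,
                           sc = sc)
    rec$method <- method
    rec$water_motif <- wm
    records[[length(records) + 1]] <- rec
  }
  records
}

## rebuild the scanned neighbor at a chosen scan cell (backbone bin +
## residue identity)
scan_apply_best <- function(ext, anchor_idx, cell, cfg) {
  neighbor <- anchor_idx + 1L
  shaped <- scan_set_neighbor(ext, anchor_idx, neighbor, "after",
                              cell$phi, cell$psi)
  br <- best_rotamer_at(shaped, neighbor, cell$code, cfg)
  out <- br$pose
  attr(out, "anchor_index") <- anchor_idx
  out
}
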