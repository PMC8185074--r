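## Synthetic fixtures: a toy receptor (rigid cleft with catalytic zinc
## and two structural waters, emulating a metalloenzyme active-site
## channel), scaffold macrocycle libraries, and dose-response tables.
## Everything is deterministic per seed and ships with a manifest of the
## planted features, so tests assert against the manifest rather than
## magic numbers.

rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b); c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- cross3(a, p); v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * (1 - c_) / sum(v^2)
}

#' Place a single rigid pseudo-residue
#'
#' Builds one residue from ideal internal coordinates and rigidly places
#' it with its CA at `at` and its side chain (CB) pointing along `dir`;
#' the backbone N->C axis is aligned with `align` (projected
#' perpendicular to `dir`), then spun by `spin` degrees about `dir`.
#' The building block of toy-receptor walls and slab fixtures.
#'
#' @param code residue code
#' @param at CA position (A)
#' @param dir side-chain direction (3-vector)
#' @param align optional backbone alignment direction
#' @param spin extra rotation about `dir` (deg)
#' @return a residue `list(code=, atoms=)`
#' @export
place_pseudo_residue <- function(code, at, dir, align = NULL, spin = 0) {
  p <- build_peptide(code, c(-60, -45, 180))
  res <- p$residues[[1]]
  ca <- res$atoms["CA", ]
  cb <- if ("CB" %in% rownames(res$atoms)) res$atoms["CB", ]
        else res$atoms["C", ]
  R1 <- rotation_between(cb - ca, dir)
  m <- sweep(res$atoms, 2, ca) %*% t(R1)
  rownames(m) <- rownames(res$atoms)
  u <- dir / sqrt(sum(dir^2))
  th <- spin * pi / 180
  if (!is.null(align)) {
    v <- m["C", ] - m["N", ]
    vp <- v - sum(v * u) * u
    wp <- align - sum(align * u) * u
    if (sqrt(sum(vp^2)) > 1e-9 && sqrt(sum(wp^2)) > 1e-9)
      th <- th + atan2(sum(cross3(vp, wp) * u), sum(vp * wp))
  }
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R2 <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  m2 <- m %*% t(R2)
  m2 <- sweep(m2, 2, at, `+`)
  rownames(m2) <- rownames(m)
  list(code = res$code, atoms = m2)
}

#' Specification for a toy receptor fixture
#'
#' @param seed RNG seed (controls pseudo-residue spins)
#' @param pocket_radius cylindrical pocket radius (A)
#' @param pocket_depth depth of the cleft below the rim (A)
#' @param zinc place a catalytic zinc at the pocket base
#' @param n_structural_waters structural waters at the rim
#' @param hydrophobic_patch optional 3-vector: center of an extra
#'   hydrophobic shelf (LEU pseudo-residues) planted near the rim
#' @return a `ToyReceptorSpec` list
#' @export
toy_receptor_spec <- function(seed = 1, pocket_radius = 6.5,
                              pocket_depth = 9, zinc = TRUE,
                              n_structural_waters = 2,
                              hydrophobic_patch = NULL) {
  if (pocket_depth < 0) stop("impossible geometry: pocket_depth < 0")
  structure(list(seed = seed, pocket_radius = pocket_radius,
                 pocket_depth = pocket_depth, zinc = zinc,
                 n_structural_waters = n_structural_waters,
                 hydrophobic_patch = hydrophobic_patch),
            class = "ToyReceptorSpec")
}

#' Generate a toy receptor: rigid cleft + zinc + structural waters
#'
#' A cylindrical cup of poly-alanine pseudo-residues (side chains lining
#' the cavity) around a vertical channel, with the zinc at the base and
#' structural waters at the rim. The pocket opens along +z; the zinc
#' sits at `(0, 0, -pocket_depth + 1.5)`.
#'
#' @param spec a `ToyReceptorSpec` (see [toy_receptor_spec()])
#' @return list with `pose` (chain "A") and `manifest` (planted feature
#'   coordinates and expected counts)
#' @export
make_toy_receptor <- function(spec = toy_receptor_spec()) {
  set.seed(spec$seed)
  residues <- list()
  add <- function(r) residues[[length(residues) + 1]] <<- r
  rad <- spec$pocket_radius
  ## wall rings: backbones run along the ring tangent, side chains
  ## point into the cavity
  for (z in seq(-spec$pocket_depth + 1, 1, by = 3.8)) {
    n_ring <- max(6, round(2 * pi * rad / 5.2))
    for (k in seq_len(n_ring)) {
      th <- 2 * pi * (k - 1) / n_ring + (z * 0.35)
      at <- c(rad * cos(th), rad * sin(th), z)
      dir <- -c(cos(th), sin(th), 0)
      tangent <- c(-sin(th), cos(th), 0)
      add(place_pseudo_residue("ALA", at, dir, align = tangent,
                               spin = runif(1, -12, 12)))
    }
  }
  ## floor disk
  zf <- -spec$pocket_depth - 2.4
  for (rr in c(0, 3.6)) {
    nk <- if (rr == 0) 1 else round(2 * pi * rr / 5.4)
    for (k in seq_len(nk)) {
      th <- 2 * pi * (k - 1) / max(nk, 1)
      at <- c(rr * cos(th), rr * sin(th), zf)
      add(place_pseudo_residue("ALA", at, c(0, 0, 1),
                               align = c(-sin(th), cos(th), 0),
                               spin = runif(1, -12, 12)))
    }
  }
  patch <- NULL
  if (!is.null(spec$hydrophobic_patch)) {
    ctr <- spec$hydrophobic_patch
    for (dxy in list(c(0, 0), c(3.6, 0), c(0, 3.6), c(3.6, 3.6))) {
      at <- ctr + c(dxy, 0)
      add(place_pseudo_residue("LEU", at, c(0, 0, -1),
                               align = c(1, 0, 0),
                               spin = runif(1, -12, 12)))
    }
    patch <- ctr
  }
  zinc <- list()
  zn_pos <- NULL
  if (spec$zinc) {
    zn_pos <- c(0, 0, -spec$pocket_depth + 1.5)
    zinc <- list(list(position = zn_pos, target = 2.3))
  }
  wpos <- matrix(numeric(0), 0, 3)
  if (spec$n_structural_waters > 0) {
    ang <- seq(0, 2 * pi, length.out = spec$n_structural_waters + 1)[
      seq_len(spec$n_structural_waters)]
    wpos <- cbind(3.2 * cos(ang), 3.2 * sin(ang), 0.4)
  }
  pose <- new_pose(residues, chain = "A", cyclic = FALSE, zinc = zinc,
                   waters = list(positions = wpos,
                                 structural = rep(TRUE, nrow(wpos))))
  manifest <- list(seed = spec$seed, version = 1L,
                   n_residues = length(residues),
                   zinc = zn_pos, waters = wpos,
                   hydrophobic_patch = patch,
                   pocket_radius = spec$pocket_radius,
                   pocket_depth = spec$pocket_depth)
  list(pose = pose, manifest = manifest)
}

#' Place the anchor residue in a toy receptor pocket
#'
#' Builds the thiol anchor inside the pocket with its side chain
#' extended toward the zinc so the terminal sulfur sits at the target
#' coordination distance; the peptide backbone is at the pocket mouth.
#'
#' @param receptor toy receptor `pose`
#' @param anchor_code anchor residue code
#' @return complex `Pose` (receptor chain "A" + anchor chain "P")
#' @export
seed_anchor_in_pocket <- function(receptor, anchor_code = "SHA") {
  zn <- receptor$zinc[[1]]
  ## anchor placed with side chain pointing down the channel
  p <- build_peptide(anchor_code, c(-60, -45, 180),
                     chis = list(rep(180, 8)))
  res <- p$residues[[1]]
  s_name <- intersect(c("SH", "SG"), rownames(res$atoms))[1]
  ca <- res$atoms["CA", ]; s <- res$atoms[s_name, ]
  R <- rotation_between(s - ca, c(0, 0, -1))
  m <- sweep(res$atoms, 2, ca) %*% t(R)
  ## slide along z so the S sits `target` above the zinc
  m <- sweep(m, 2, -m[s_name, ], `+`)
  target_s <- zn$position + c(0, 0, zn$target)
  m <- sweep(m, 2, target_s, `+`)
  rownames(m) <- rownames(res$atoms)
  anchor_pose <- new_pose(list(list(code = res$code, atoms = m)),
                          chain = "P")
  pose_merge(receptor, anchor_pose)
}

#' Generate a library of toy macrocycle scaffolds
#'
#' Closed 7-10 residue macrocycles of mixed glycine / L- and D-alanine,
#' emulating a pre-generated structured-scaffold library.
#'
#' @param n number of scaffolds
#' @param size_range inclusive residue-count range
#' @param seed RNG seed
#' @param cfg configuration
#' @return list of cyclic `Pose` objects (attribute `"manifest"`)
#' @export
make_scaffold_library <- function(n, size_range = c(7, 10), seed = 1,
                                  cfg = ax_config()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n, replace = TRUE)
  seeds <- sample.int(2^30, n)
  out <- list()
  for (i in seq_len(n)) {
    codes <- sample(c("GLY", "ALA", "DAL"), sizes[i], replace = TRUE)
    ens <- sample_closed_ensemble(codes, 1, seed = seeds[i], cfg = cfg,
                                  max_attempts = 400)
    if (length(ens) == 0) {
      warning("scaffold ", i, ": closure budget exhausted, skipped")
      next
    }
    out[[length(out) + 1]] <- ens[[1]]
  }
  attr(out, "manifest") <- list(seed = seed, sizes = sizes,
                                produced = length(out))
  out
}

#' The four-parameter logistic (dose-response) curve
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^((log10(IC50) - X) * Hill))`
#' with `X = log10(concentration)`. With `bottom = 0`, the curve passes
#' `top / 2` exactly at the IC50. Under this parameterization an
#' inhibition curve (activity falling with concentration) has a negative
#' Hill slope.
#'
#' @param conc concentrations (molar)
#' @param ic50 IC50 (molar)
#' @param hill Hill slope
#' @param top,bottom plateau parameters (% activity)
#' @return predicted activities (%)
#' @export
logistic4 <- function(conc, ic50, hill, top, bottom = 0) {
  x <- log10(conc)
  bottom + (top - bottom) / (1 + 10^((log10(ic50) - x) * hill))
}

#' Simulate a dose-response table
#'
#' Serial-dilution design spanning 1 uM to 100 pM: `n_points`
#' log-spaced concentrations over `[c_min, c_max]` (the default 5
#' points reproduce the 1:10 dilution series), activities from the
#' four-parameter logistic plus Gaussian noise.
#'
#' @param ic50 true IC50 (molar)
#' @param hill true Hill slope (negative = inhibition direction)
#' @param top true top plateau (%)
#' @param noise_sd Gaussian noise: the standard deviation equals this
#'   percentage of each predicted activity (relative noise)
#' @param seed RNG seed
#' @param c_max,c_min concentration range (molar)
#' @param n_points number of concentrations
#' @param replicates replicate series
#' @return data.frame of class `DoseResponse`: concentration_M,
#'   activity_pct, replicate
#' @export
make_dose_response <- function(ic50, hill = -1, top = 100, noise_sd = 0,
                               seed = 1, c_max = 1e-6, c_min = 1e-10,
                               n_points = 5, replicates = 1) {
  if (ic50 <= 0) stop("ic50 must be positive")
  set.seed(seed)
  conc <- 10^seq(log10(c_max), log10(c_min), length.out = n_points)
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    y0 <- logistic4(conc, ic50, hill, top)
    y <- y0 * (1 + rnorm(n_points, 0, noise_sd / 100))
    data.frame(concentration_M = conc, activity_pct = y, replicate = r)
  }))
  class(out) <- c("DoseResponse", class(out))
  out
}

#' Paired structured / flexible toy macrocycles for funnel analysis
#'
#' Constructs the benchmark pair used to validate funnel discrimination:
#' a "structured" macrocycle (salt-bridge- and proline-stabilized, whose
#' reference conformation is the energy minimum of a deep conformer
#' probe) and a "flexible" one (glycine-rich, whose reference is a
#' median-energy conformer -- a binding-like conformation that is not
#' the free-state minimum). Deterministic given `probe_seed`.
#'
#' @param probe_seed seed for the reference-defining conformer probes
#' @param cfg configuration
#' @return list with `structured` and `flexible`, each
#'   `list(sequence=, design_pose=)`
#' @export
make_funnel_pair <- function(probe_seed = 999, cfg = ax_config()) {
  strc <- c("GLU", "PRO", "GLY", "ARG", "GLY", "GLY", "GLY")
  flex <- c("SER", "GLY", "GLY", "GLY", "GLY", "GLY", "GLY")
  es <- sample_closed_ensemble(strc, 55, seed = probe_seed, cfg = cfg,
                               max_attempts = 18000)
  ef <- sample_closed_ensemble(flex, 30, seed = probe_seed, cfg = cfg,
                               max_attempts = 6000)
  eng <- function(ens) vapply(ens, function(p)
    as.numeric(total_energy(p, cfg)), numeric(1))
  fe <- eng(ef)
  list(structured = list(sequence = strc,
                         design_pose = es[[which.min(eng(es))]]),
       flexible = list(sequence = flex,
                       design_pose = ef[[order(fe)[ceiling(length(fe) / 2)]]]))
}
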