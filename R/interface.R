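## Interface metrics: contacts, clashes, solvent accessibility, buried
## unsatisfied polar atoms, and the shape-complementarity statistic.

#' Count inter-chain heavy-atom contacts
#'
#' @param complex_pose a `Pose` with at least two chains
#' @param chainA,chainB chain ids (defaults: first chain vs the rest)
#' @param cutoff contact distance (A); pairs strictly closer count
#' @return integer
#' @export
count_contacts <- function(complex_pose, chainA = NULL, chainB = NULL,
                           cutoff = 4.5) {
  df <- pose_atoms(complex_pose, include_het = FALSE)
  ch <- unique(df$chain)
  if (is.null(chainA)) chainA <- ch[length(ch)]
  if (is.null(chainB)) chainB <- setdiff(ch, chainA)
  a <- coords_matrix(df[df$chain %in% chainA, , drop = FALSE])
  b <- coords_matrix(df[df$chain %in% chainB, , drop = FALSE])
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  count_close_pairs_cpp(a, b, cutoff)
}

#' Count steric clashes in a pose
#'
#' Non-bonded heavy-atom pairs (separated by more than 3 bonds, or on
#' different chains) closer than the sum of vdW radii minus `overlap`.
#' Waters participate; zinc does not.
#'
#' @param pose a `Pose`
#' @param overlap allowed overlap (A)
#' @return integer
#' @export
clash_count <- function(pose, overlap = 0.5) {
  df <- pose_atoms(pose, include_het = TRUE)
  df <- df[df$element != "ZN", , drop = FALSE]
  n <- nrow(df)
  if (n < 2) return(0L)
  xyz <- coords_matrix(df)
  poly <- pose_atoms(pose, include_het = FALSE)
  excl <- bonded_exclusions(pose, poly)
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(df$radius, df$radius, `+`) - overlap
  hit <- d < lim
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  if (ncol(excl) > 0)
    for (j in seq_len(ncol(excl)))
      hit[min(excl[, j]), max(excl[, j])] <- FALSE
  as.integer(sum(hit))
}

## golden-spiral unit sphere points
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' @param coords n x 3 heavy-atom coordinates
#' @param radii vdW radii (A)
#' @param probe probe radius (A)
#' @param n_dots test points per atom
#' @return numeric vector of per-atom SASA (A^2)
#' @export
sasa_atoms <- function(coords, radii, probe = 1.4, n_dots = 92) {
  n <- nrow(coords)
  sp <- sphere_points(n_dots)
  out <- numeric(n)
  rext <- radii + probe
  for (i in seq_len(n)) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    nb <- which(d2 < (rext[i] + rext)^2 & seq_len(n) != i)
    dots <- sweep(sp * rext[i], 2, coords[i, ], `+`)
    free <- rep(TRUE, n_dots)
    for (j in nb) {
      dd <- colSums((t(dots) - coords[j, ])^2)
      free <- free & dd > rext[j]^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * rext[i]^2 * sum(free) / n_dots
  }
  out
}

#' Buried unsatisfied polar atoms of a complex
#'
#' Polar heavy atoms (donors/acceptors, waters count as partners) whose
#' SASA in the complex is below the burial threshold and that have no
#' complementary polar partner within hydrogen-bonding distance.
#'
#' @param complex_pose a `Pose`
#' @param cfg configuration (`sasa_probe`, `sasa_buried`,
#'   `hbond_partner_max`)
#' @return integer count
#' @export
buried_unsats <- function(complex_pose, cfg = ax_config()) {
  df <- pose_atoms(complex_pose, include_het = TRUE)
  df <- df[df$element != "ZN", , drop = FALSE]
  xyz <- coords_matrix(df)
  sasa <- sasa_atoms(xyz, df$radius, probe = cfg$sasa_probe)
  polar <- df$role != "none"
  buried <- polar & sasa < cfg$sasa_buried
  if (!any(buried)) return(0L)
  poly <- pose_atoms(complex_pose, include_het = FALSE)
  excl <- bonded_exclusions(complex_pose, poly)
  excl_set <- if (ncol(excl)) paste(pmin(excl[1, ], excl[2, ]),
                                    pmax(excl[1, ], excl[2, ])) else character(0)
  don <- df$role %in% c("donor", "both")
  acc <- df$role %in% c("acceptor", "both")
  unsat <- 0L
  for (i in which(buried)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    cand <- which(d < cfg$hbond_partner_max & seq_len(nrow(df)) != i)
    cand <- cand[(don[i] & acc[cand]) | (acc[i] & don[cand])]
    if (length(cand)) {
      keys <- paste(pmin(i, cand), pmax(i, cand))
      cand <- cand[!keys %in% excl_set]
    }
    if (length(cand) == 0) unsat <- unsat + 1L
  }
  unsat
}

## van der Waals surface dots of a chain: per-atom sphere dots kept when
## not inside any other atom of the same chain. Returns dot coordinates
## and outward normals.
surface_dots <- function(coords, radii, density) {
  dots <- list(); normals <- list()
  n <- nrow(coords)
  for (i in seq_len(n)) {
    nd <- max(12, round(4 * pi * radii[i]^2 * density))
    sp <- sphere_points(nd)
    pts <- sweep(sp * radii[i], 2, coords[i, ], `+`)
    d2 <- colSums((t(coords) - coords[i, ])^2)
    nb <- which(d2 < (radii[i] + radii)^2 & seq_len(n) != i)
    free <- rep(TRUE, nd)
    for (j in nb) {
      dd <- colSums((t(pts) - coords[j, ])^2)
      free <- free & dd > (radii[j] * 0.999)^2
    }
    if (any(free)) {
      dots[[length(dots) + 1]] <- pts[free, , drop = FALSE]
      normals[[length(normals) + 1]] <- sp[free, , drop = FALSE]
    }
  }
  list(points = do.call(rbind, dots), normals = do.call(rbind, normals))
}

## for each dot in a, index of nearest dot in b (chunked distances)
nearest_dot <- function(a, b, chunk = 2000) {
  n <- nrow(a)
  idx <- integer(n); dmin <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    block <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(b^2), `+`) -
      2 * block %*% t(b)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dmin[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(block)), j)]))
  }
  list(index = idx, dist = dmin)
}

#' Shape complementarity of a two-chain interface
#'
#' Median-based dot statistic over facing molecular-surface points: for
#' each interface dot, `s = -(n_a . n_b) * exp(-w d^2)` against the
#' nearest dot of the partner surface; the statistic is the mean of the
#' two directional medians. 1 = perfect fit; values below ~0.5 indicate
#' poorly matching surfaces.
#'
#' @param complex_pose a `Pose`
#' @param chainA,chainB chain ids of the two sides
#' @param cfg configuration (`sc_density` dots/A^2, `sc_weight` 1/A^2,
#'   `sc_band` interface band A)
#' @param density override the dot density (dots/A^2)
#' @return numeric in `[-1, 1]`
#' @export
shape_complementarity <- function(complex_pose, chainA = NULL, chainB = NULL,
                                  cfg = ax_config(), density = NULL) {
  df <- pose_atoms(complex_pose, include_het = FALSE)
  ch <- unique(df$chain)
  if (is.null(chainA)) chainA <- ch[1]
  if (is.null(chainB)) chainB <- setdiff(ch, chainA)[1]
  if (is.null(density)) density <- cfg$sc_density
  a_df <- df[df$chain %in% chainA, , drop = FALSE]
  b_df <- df[df$chain %in% chainB, , drop = FALSE]
  a_xyz <- coords_matrix(a_df); b_xyz <- coords_matrix(b_df)
  if (count_close_pairs_cpp(a_xyz, b_xyz, 8) == 0)
    stop("no interface: chains ", paste(chainA, collapse = "+"), " and ",
         paste(chainB, collapse = "+"), " are out of contact range")
  ## only atoms near the other chain contribute surface worth dotting
  near_a <- apply(a_xyz, 1, function(p)
    min(colSums((t(b_xyz) - p)^2))) < 144
  near_b <- apply(b_xyz, 1, function(p)
    min(colSums((t(a_xyz) - p)^2))) < 144
  sa <- surface_dots(a_xyz[near_a, , drop = FALSE],
                     a_df$radius[near_a], density)
  sb <- surface_dots(b_xyz[near_b, , drop = FALSE],
                     b_df$radius[near_b], density)
  ## distance from each dot to the partner's sphere-union surface is
  ## exact (min over partner atoms of |x - c| - r); the nearest atom
  ## also supplies the partner surface normal. Dots are only the
  ## integration points of the median, so the statistic is nearly
  ## independent of dot density.
  med <- function(from, part_xyz, part_r) {
    np <- nrow(from$points)
    dmin <- rep(Inf, np); jmin <- integer(np)
    for (j in seq_len(nrow(part_xyz))) {
      dj <- sqrt(colSums((t(from$points) - part_xyz[j, ])^2)) - part_r[j]
      upd <- dj < dmin
      dmin[upd] <- dj[upd]; jmin[upd] <- j
    }
    keep <- dmin < cfg$sc_band
    if (sum(keep) < 5) return(NA_real_)
    pn <- from$points[keep, , drop = FALSE] -
      part_xyz[jmin[keep], , drop = FALSE]
    pn <- pn / sqrt(rowSums(pn^2))
    s <- -rowSums(from$normals[keep, , drop = FALSE] * pn) *
      exp(-cfg$sc_weight * pmax(dmin[keep], 0)^2)
    median(s)
  }
  m1 <- med(sa, b_xyz[near_b, , drop = FALSE], b_df$radius[near_b])
  m2 <- med(sb, a_xyz[near_a, , drop = FALSE], a_df$radius[near_a])
  if (is.na(m1) || is.na(m2))
    stop("no interface: too few buried surface dots")
  mean(c(m1, m2))
}

#' Interface metric report for a designed complex
#'
#' @param complex_pose a `Pose`
#' @param peptide_chain peptide chain id
#' @param cfg configuration
#' @param sc compute shape complementarity (the slowest metric)
#' @return list of class `InterfaceReport`: ddg, sc, contacts,
#'   buried_unsats, clashes
#' @export
interface_report <- function(complex_pose, peptide_chain = "P",
                             cfg = ax_config(), sc = TRUE) {
  rec_chains <- setdiff(unique(complex_pose$chain), peptide_chain)
  sc_val <- if (sc) tryCatch(
    shape_complementarity(complex_pose, rec_chains, peptide_chain, cfg),
    error = function(e) NA_real_) else NA_real_
  structure(list(
    ddg = ddg_bind(complex_pose, peptide_chain, repack = FALSE, cfg = cfg),
    sc = sc_val,
    contacts = count_contacts(complex_pose, peptide_chain, rec_chains,
                              cfg$contact_cutoff),
    buried_unsats = buried_unsats(complex_pose, cfg),
    clashes = clash_count(complex_pose, cfg$clash_overlap)),
    class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf(
    "InterfaceReport: ddg=%.2f sc=%.3f contacts=%d unsats=%d clashes=%d\n",
    x$ddg, x$sc, x$contacts, x$buried_unsats, x$clashes))
  invisible(x)
}
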