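## Independent brute-force oracles. These deliberately avoid the
## package's computational paths (plain R double loops, direct formulas)
## so that metric tests compare two independent routes.

## dihedral by projecting the outer bonds onto the plane perpendicular
## to the central bond (textbook definition; verified against the
## planar 180/0 and +90 reference cases below)
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  a <- (p1 - p2) - sum((p1 - p2) * u) * u
  d <- (p4 - p3) - sum((p4 - p3) * u) * u
  atan2(sum(cr(u, a) * d), sum(a * d)) * 180 / pi
}

## inter-chain contacts by explicit double loop
oracle_contacts <- function(complex_pose, chainA, chainB, cutoff = 4.5) {
  df <- pose_atoms(complex_pose, include_het = FALSE)
  a <- df[df$chain %in% chainA, ]; b <- df[df$chain %in% chainB, ]
  cnt <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
              (a$z[i] - b$z[j])^2)
    if (d < cutoff) cnt <- cnt + 1L
  }
  cnt
}

## clash count by explicit double loop with the same exclusion rule
oracle_clashes <- function(pose, overlap = 0.5) {
  df <- pose_atoms(pose, include_het = TRUE)
  df <- df[df$element != "ZN", ]
  excl <- bonded_exclusions(pose, pose_atoms(pose, include_het = FALSE))
  ek <- if (ncol(excl)) paste(pmin(excl[1, ], excl[2, ]),
                              pmax(excl[1, ], excl[2, ])) else character(0)
  cnt <- 0L
  for (i in seq_len(nrow(df) - 1)) for (j in (i + 1):nrow(df)) {
    if (paste(i, j) %in% ek) next
    d <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
              (df$z[i] - df$z[j])^2)
    if (d < df$radius[i] + df$radius[j] - overlap) cnt <- cnt + 1L
  }
  cnt
}

## binding energy gap by direct double-loop summation of the inter-chain
## pairwise terms plus the zinc restraint (valid for repack = FALSE,
## where intra-chain terms cancel exactly)
oracle_ddg <- function(complex_pose, peptide_chain, cfg = ax_config()) {
  df <- pose_atoms(complex_pose, include_het = TRUE)
  df <- df[df$element != "ZN", ]
  pep <- which(df$chain == peptide_chain)
  oth <- which(!df$chain %in% c(peptide_chain))
  tot <- 0
  for (i in pep) for (j in oth) {
    d <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
              (df$z[i] - df$z[j])^2)
    if (d > cfg$nb_cutoff) next
    s <- df$radius[i] + df$radius[j]
    deff <- max(d, 0.6 * s)
    r6 <- (s / deff)^6
    e <- cfg$lj_eps * (r6^2 - 2 * r6)
    if (d < s) tot <- tot + cfg$w_rep * (e + cfg$lj_eps) +
        cfg$w_atr * (-cfg$lj_eps)
    else tot <- tot + cfg$w_atr * e
    don_i <- df$role[i] %in% c("donor", "both")
    acc_i <- df$role[i] %in% c("acceptor", "both")
    don_j <- df$role[j] %in% c("donor", "both")
    acc_j <- df$role[j] %in% c("acceptor", "both")
    if (d < cfg$hb_max && ((don_i && acc_j) || (don_j && acc_i)))
      tot <- tot + cfg$w_hb *
        (-cfg$hb_depth * exp(-0.5 * ((d - cfg$hb_ideal) / cfg$hb_sd)^2))
    if (df$charge[i] != 0 && df$charge[j] != 0)
      tot <- tot + cfg$w_elec * 332 * df$charge[i] * df$charge[j] /
        (cfg$elec_eps * d) * exp(-d / cfg$elec_kappa)
  }
  ## zinc restraint exists only in the complex state
  for (zn in complex_pose$zinc) {
    s_idx <- which(df$element == "S" & df$chain == peptide_chain)
    if (length(s_idx) == 0) next
    dmin <- min(sqrt((df$x[s_idx] - zn$position[1])^2 +
                     (df$y[s_idx] - zn$position[2])^2 +
                     (df$z[s_idx] - zn$position[3])^2))
    tot <- tot + cfg$w_zn * (dmin - zn$target)^2
  }
  tot
}

## shape complementarity with a dense independent dot implementation
oracle_sc <- function(complex_pose, chainA, chainB, density = 25,
                      w = 0.5, band = 1.5) {
  df <- pose_atoms(complex_pose, include_het = FALSE)
  side <- function(chains) {
    sub <- df[df$chain %in% chains, ]
    pts <- NULL; nrm <- NULL
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    for (i in seq_len(nrow(sub))) {
      r <- sub$radius[i]
      nd <- max(12, round(4 * pi * r^2 * density))
      gold <- pi * (1 + sqrt(5)) * (seq_len(nd) - 0.5)
      cphi <- 1 - 2 * (seq_len(nd) - 0.5) / nd
      sphi <- sqrt(pmax(0, 1 - cphi^2))
      sp <- cbind(sphi * cos(gold), sphi * sin(gold), cphi)
      cand <- sweep(sp * r, 2, xyz[i, ], `+`)
      keep <- rep(TRUE, nd)
      for (j in seq_len(nrow(sub))) {
        if (j == i) next
        dd <- sqrt(colSums((t(cand) - xyz[j, ])^2))
        keep <- keep & dd > sub$radius[j] * 0.999
      }
      pts <- rbind(pts, cand[keep, , drop = FALSE])
      nrm <- rbind(nrm, sp[keep, , drop = FALSE])
    }
    list(p = pts, n = nrm)
  }
  A <- side(chainA); B <- side(chainB)
  ## only dots within 6 A of a partner atom can be interface dots
  trim <- function(side_dots, partner_xyz) {
    keep <- rep(FALSE, nrow(side_dots$p))
    for (j in seq_len(nrow(partner_xyz))) {
      dd <- colSums((t(side_dots$p) - partner_xyz[j, ])^2)
      keep <- keep | dd < 36
    }
    list(p = side_dots$p[keep, , drop = FALSE],
         n = side_dots$n[keep, , drop = FALSE])
  }
  axyz <- as.matrix(df[df$chain %in% chainA, c("x", "y", "z")])
  bxyz <- as.matrix(df[df$chain %in% chainB, c("x", "y", "z")])
  A <- trim(A, bxyz); B <- trim(B, axyz)
  direction <- function(from, to) {
    s <- numeric(0)
    for (i in seq_len(nrow(from$p))) {
      dd <- sqrt(colSums((t(to$p) - from$p[i, ])^2))
      j <- which.min(dd)
      if (dd[j] < band)
        s <- c(s, -sum(from$n[i, ] * to$n[j, ]) * exp(-w * dd[j]^2))
    }
    median(s)
  }
  mean(c(direction(A, B), direction(B, A)))
}

## Pnear by direct evaluation of the weighted sum
oracle_pnear <- function(energy, rmsd, lambda = 1.5, kT = 1) {
  w <- exp(-(energy - min(energy)) / kT)
  sum(exp(-rmsd^2 / lambda^2) * w) / sum(w)
}
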