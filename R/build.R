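## Building chains from ideal internal coordinates (NeRF), measuring
## backbone/side-chain torsions, and torsion moves.

## R-side single-atom NeRF placement (mirrors the compiled kernel; used
## for one-off placements such as side-chain grafting).
nerf_place_r <- function(A, B, C, bond, angle, torsion) {
  ab <- A - B; bc <- B - C
  ab <- ab / sqrt(sum(ab^2))
  n <- cross3(bc, ab); n <- n / sqrt(sum(n^2))
  m <- cross3(n, ab)
  th <- angle * pi / 180; ph <- torsion * pi / 180
  A + (-bond * cos(th)) * ab + (bond * sin(th) * cos(ph)) * m +
    (bond * sin(th) * sin(ph)) * n
}

## Compile a linear chain of residue codes into an internal-coordinate
## table consumable by ic_build_cpp. Free-torsion vector layout:
## per residue, phi / psi / omega / chi1..chiK, named e.g. "phi_2".
## The first residue's N, CA, C are roots (fixed coordinates).
compile_chain <- function(codes, root_coords = NULL) {
  ## topology depends only on the code sequence: memoize it
  key <- paste(codes, collapse = "|")
  cached <- .ax_env$cc_cache[[key]]
  if (!is.null(cached)) {
    if (!is.null(root_coords)) cached$coords_init[1:3, ] <- root_coords
    return(cached)
  }
  out <- compile_chain_impl(codes)
  if (is.null(.ax_env$cc_cache)) .ax_env$cc_cache <- list()
  if (length(.ax_env$cc_cache) > 200) .ax_env$cc_cache <- list()
  .ax_env$cc_cache[[key]] <- out
  if (!is.null(root_coords)) out$coords_init[1:3, ] <- root_coords
  out
}

compile_chain_impl <- function(codes) {
  tpls <- lapply(codes, get_template)
  n <- length(codes)
  tor_names <- character(0)
  for (i in seq_len(n)) {
    tor_names <- c(tor_names,
                   sprintf(c("phi_%d", "psi_%d", "omega_%d"), i),
                   if (tpls[[i]]$n_chi > 0)
                     sprintf("chi%d_%d", seq_len(tpls[[i]]$n_chi), i))
  }
  tor_idx_of <- setNames(seq_along(tor_names), tor_names)

  atom_res <- integer(0)
  refs <- list(); geom <- list(); tidx <- integer(0)
  flat_names <- character(0)
  for (i in seq_len(n)) {
    tpl <- tpls[[i]]
    for (k in seq_len(nrow(tpl$atoms))) {
      a <- tpl$atoms[k, ]
      row_id <- length(flat_names) + 1
      is_root <- i == 1 && a$name %in% c("N", "CA", "C")
      if (is_root) {
        refs[[row_id]] <- c(0L, 0L, 0L)
        geom[[row_id]] <- c(0, 0, 0)
        tidx[row_id] <- 0L
      } else {
        resolve <- function(r) {
          if (startsWith(r, "-")) {
            if (i == 1) stop("residue 1 atom ", a$name,
                             " needs a preceding residue")
            match(paste(i - 1, substring(r, 2)),
                  paste(atom_res, flat_names))
          } else match(paste(i, r), paste(atom_res, flat_names))
        }
        r1 <- resolve(a$ref1); r2 <- resolve(a$ref2); r3 <- resolve(a$ref3)
        if (any(is.na(c(r1, r2, r3))))
          stop("unresolved reference atoms for ", a$name, " in residue ", i)
        p <- parse_torsion_expr(a$torsion)
        ## N's psi and CA's omega belong to the preceding residue
        own <- i - (a$name == "N" && p$kind == "psi") -
                   (a$name == "CA" && p$kind == "omega")
        ti <- switch(p$kind,
                     fixed = 0L,
                     phi = tor_idx_of[sprintf("phi_%d", own)],
                     psi = tor_idx_of[sprintf("psi_%d", own)],
                     omega = tor_idx_of[sprintf("omega_%d", own)],
                     chi = tor_idx_of[sprintf("chi%d_%d", p$idx, own)])
        refs[[row_id]] <- c(r1, r2, r3)
        geom[[row_id]] <- c(a$bond, a$angle, p$offset)
        tidx[row_id] <- as.integer(ti)
      }
      flat_names <- c(flat_names, a$name)
      atom_res <- c(atom_res, i)
    }
  }
  refs <- do.call(rbind, refs)
  geom <- do.call(rbind, geom)
  g <- BACKBONE_GEOM
  th <- (180 - g$a_n_ca_c) * pi / 180
  root_coords <- rbind(N = c(0, 0, 0),
                       CA = c(g$b_n_ca, 0, 0),
                       C = c(g$b_n_ca + g$b_ca_c * cos(th),
                             g$b_ca_c * sin(th), 0))
  coords_init <- matrix(0, nrow(refs), 3)
  coords_init[1:3, ] <- root_coords
  list(codes = codes, templates = tpls, refs = refs, geom = geom,
       tor_idx = tidx, tor_names = tor_names, atom_names = flat_names,
       atom_res = atom_res, coords_init = coords_init)
}

## Assemble a named free-torsion vector for compile_chain output.
## torsions: n x 3 matrix/data.frame (phi, psi, omega); chis: list per
## residue (padded with rotamer defaults).
torsion_vector <- function(cc, torsions, chis = NULL) {
  n <- length(cc$codes)
  torsions <- as.matrix(torsions)
  tv <- setNames(numeric(length(cc$tor_names)), cc$tor_names)
  for (i in seq_len(n)) {
    tv[sprintf("phi_%d", i)] <- torsions[i, 1]
    tv[sprintf("psi_%d", i)] <- torsions[i, 2]
    tv[sprintf("omega_%d", i)] <- torsions[i, 3]
    nchi <- cc$templates[[i]]$n_chi
    if (nchi > 0) {
      ch <- if (!is.null(chis) && length(chis) >= i && !is.null(chis[[i]]))
        chis[[i]] else cc$templates[[i]]$rotamers[1, ]
      ch <- rep_len(ch, nchi)
      tv[sprintf("chi%d_%d", seq_len(nchi), i)] <- ch
    }
  }
  tv
}

ic_to_pose <- function(cc, coords, chain = "P", cyclic = FALSE) {
  residues <- vector("list", length(cc$codes))
  for (i in seq_along(cc$codes)) {
    sel <- cc$atom_res == i
    m <- coords[sel, , drop = FALSE]
    rownames(m) <- cc$atom_names[sel]
    residues[[i]] <- list(code = cc$codes[i], atoms = m)
  }
  new_pose(residues, chain = chain, cyclic = cyclic)
}

#' Build a peptide chain from ideal internal coordinates
#'
#' @param codes character vector of registered residue codes
#' @param torsions n x 3 matrix or data.frame of (phi, psi, omega) in
#'   degrees; a single row is recycled
#' @param chis optional list of chi vectors per residue
#' @param chain chain id
#' @param cyclic mark the pose head-to-tail cyclic (geometry is whatever
#'   the torsions give; see [close_macrocycle()] to actually close)
#' @return a `Pose`
#' @export
build_peptide <- function(codes, torsions = c(-60, -45, 180), chis = NULL,
                          chain = "P", cyclic = FALSE) {
  for (code in codes)
    if (!template_exists(code)) stop("unknown residue code: ", code)
  if (is.null(dim(torsions)))
    torsions <- matrix(torsions, length(codes), 3, byrow = TRUE)
  cc <- compile_chain(codes)
  tv <- torsion_vector(cc, torsions, chis)
  coords <- ic_build_cpp(cc$refs, cc$geom, cc$tor_idx, tv, cc$coords_init)
  ic_to_pose(cc, coords, chain = chain, cyclic = cyclic)
}

#' Measure backbone and side-chain torsions of a pose
#'
#' @param pose a `Pose`
#' @return data.frame with resno, code, phi, psi, omega (NA where
#'   undefined) and a `chis` list-column
#' @export
pose_torsions <- function(pose) {
  n <- pose_size(pose)
  phi <- psi <- omg <- rep(NA_real_, n)
  chis <- vector("list", n)
  cyc <- cyclic_chains(pose)
  for (i in seq_len(n)) {
    res <- pose$residues[[i]]
    members <- which(pose$chain == pose$chain[i])
    lo <- min(members); hi <- max(members)
    is_cyc <- pose$chain[i] %in% cyc && length(members) > 1
    prev <- if (i > lo) i - 1 else if (is_cyc) hi else NA
    nxt <- if (i < hi) i + 1 else if (is_cyc) lo else NA
    N <- get_atom(pose, i, "N"); CA <- get_atom(pose, i, "CA")
    C <- get_atom(pose, i, "C")
    if (!is.na(prev) && prev != i)
      phi[i] <- dihedral(get_atom(pose, prev, "C"), N, CA, C)
    if (!is.na(nxt) && nxt != i) {
      psi[i] <- dihedral(N, CA, C, get_atom(pose, nxt, "N"))
      omg[i] <- dihedral(CA, C, get_atom(pose, nxt, "N"),
                         get_atom(pose, nxt, "CA"))
    } else if ("O" %in% rownames(res$atoms)) {
      psi[i] <- wrap_angle(dihedral(N, CA, C, get_atom(pose, i, "O")) + 180)
    }
    tpl <- get_template(res$code)
    if (tpl$n_chi > 0) {
      chis[[i]] <- vapply(tpl$chi_atoms, function(q)
        dihedral(get_atom(pose, i, q[1]), get_atom(pose, i, q[2]),
                 get_atom(pose, i, q[3]), get_atom(pose, i, q[4])),
        numeric(1))
    }
  }
  out <- data.frame(resno = seq_len(n), code = pose_sequence(pose),
                    phi = phi, psi = psi, omega = omg)
  out$chis <- chis
  out
}

## Rotate a set of residue atoms about an axis (through point `origin`,
## direction `axis`, right-handed angle deg).
rotate_atoms <- function(coords, origin, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(coords, 2, origin) %*% t(R), 2, origin, `+`)
}

## atoms moved by each torsion: subtree of the rotated bond's distal atom
torsion_subtree <- function(pose, resno, which) {
  n <- pose_size(pose)
  if (startsWith(which, "chi")) {
    tpl <- get_template(pose$residues[[resno]]$code)
    k <- as.integer(substring(which, 4))
    if (k < 1 || k > tpl$n_chi) stop("chi index out of range for ",
                                     pose$residues[[resno]]$code)
    q <- tpl$chi_atoms[[k]]
    axis_atoms <- c(q[2], q[3])  # rotate about CA-CB style bond
    ## distal side: template atoms whose parent path passes through q[3]
    nm <- tpl$atoms$name
    parent <- setNames(tpl$atoms$ref1, nm)
    in_subtree <- function(a) {
      while (a %in% nm) {
        if (a == q[3]) return(TRUE)
        if (a == q[2]) return(FALSE)
        a <- parent[[a]]
        if (startsWith(a, "-")) return(FALSE)
      }
      FALSE
    }
    moved <- nm[vapply(nm, in_subtree, logical(1)) & nm != q[3]]
    return(list(axis_from = c(resno, q[2]), axis_to = c(resno, q[3]),
                moved = cbind(resno, moved)))
  }
  members <- which(pose$chain == pose$chain[resno])
  succ <- members[members > resno]
  moved <- switch(which,
    phi = {
      nm <- rownames(pose$residues[[resno]]$atoms)
      rbind(cbind(resno, setdiff(nm, c("N", "CA"))),
            if (length(succ)) do.call(rbind, lapply(succ,
              function(i) cbind(i, rownames(pose$residues[[i]]$atoms)))))
    },
    psi = {
      rbind(cbind(resno, "O"),
            if (length(succ)) do.call(rbind, lapply(succ,
              function(i) cbind(i, rownames(pose$residues[[i]]$atoms)))))
    },
    omega = {
      if (!length(succ)) stop("omega undefined for the last residue of an open chain")
      do.call(rbind, lapply(succ, function(i) {
        nm <- rownames(pose$residues[[i]]$atoms)
        if (i == resno + 1) nm <- setdiff(nm, "N")
        cbind(i, nm)
      }))
    },
    stop("unknown torsion kind: ", which))
  axis <- switch(which,
    phi = list(from = c(resno, "N"), to = c(resno, "CA")),
    psi = list(from = c(resno, "CA"), to = c(resno, "C")),
    omega = list(from = c(resno, "C"), to = c(resno + 1, "N")))
  list(axis_from = axis$from, axis_to = axis$to, moved = moved)
}

measure_torsion <- function(pose, resno, which) {
  if (startsWith(which, "chi")) {
    k <- as.integer(substring(which, 4))
    tt <- pose_torsions(pose)
    return(tt$chis[[resno]][k])
  }
  tt <- pose_torsions(pose)
  tt[[which]][resno]
}

#' Set one torsion of a pose
#'
#' Rotates only the atoms downstream of the torsion's bond; bond lengths
#' and angles are untouched. For cyclic poses the closure bond is treated
#' as broken during the move (re-validate with [closure_geometry()]).
#'
#' @param pose a `Pose`
#' @param resno residue index
#' @param which one of "phi", "psi", "omega", "chi1".."chiK"
#' @param value target torsion in degrees
#' @return the modified `Pose`
#' @export
set_torsion <- function(pose, resno, which, value) {
  if (resno < 1 || resno > pose_size(pose)) stop("residue index out of range")
  if (startsWith(which, "chi")) {
    k <- as.integer(substring(which, 4))
    tpl <- get_template(pose$residues[[resno]]$code)
    if (is.na(k) || k < 1 || k > tpl$n_chi)
      stop("chi index out of range for ", pose$residues[[resno]]$code)
  }
  cur <- measure_torsion(pose, resno, which)
  if (is.na(cur)) stop(which, " is undefined at residue ", resno)
  delta <- wrap_angle(value - cur)
  if (abs(delta) < 1e-12) return(pose)
  st <- torsion_subtree(pose, resno, which)
  a1 <- get_atom(pose, as.integer(st$axis_from[1]), st$axis_from[2])
  a2 <- get_atom(pose, as.integer(st$axis_to[1]), st$axis_to[2])
  axis <- a2 - a1
  moved <- st$moved
  for (i in unique(as.integer(moved[, 1]))) {
    nm <- moved[as.integer(moved[, 1]) == i, 2]
    res <- pose$residues[[i]]
    sel <- rownames(res$atoms) %in% nm
    res$atoms[sel, ] <- rotate_atoms(res$atoms[sel, , drop = FALSE],
                                     a1, axis, delta)
    pose$residues[[i]] <- res
  }
  ## fix rotation handedness if the measured change came out reversed
  new <- measure_torsion(pose, resno, which)
  if (abs(wrap_angle(new - value)) > 1e-6) {
    for (i in unique(as.integer(moved[, 1]))) {
      nm <- moved[as.integer(moved[, 1]) == i, 2]
      res <- pose$residues[[i]]
      sel <- rownames(res$atoms) %in% nm
      res$atoms[sel, ] <- rotate_atoms(res$atoms[sel, , drop = FALSE],
                                       a1, axis, -2 * delta)
      pose$residues[[i]] <- res
    }
  }
  pose
}

## Grow residues before/after an anchored segment with ideal geometry.
## Forward growth reuses the compiled builder rooted on the last
## residue's (N, CA, C); backward growth places C, CA, N, O of each
## preceding residue by reverse NeRF.
grow_backward <- function(pose, code, phi_next, psi_new, omega_new = 180,
                          chis = NULL) {
  tpl <- get_template(code)
  g <- BACKBONE_GEOM
  N1 <- get_atom(pose, 1, "N"); CA1 <- get_atom(pose, 1, "CA")
  C1 <- get_atom(pose, 1, "C")
  Cp <- nerf_place_r(N1, CA1, C1, g$b_c_n, g$a_c_n_ca, phi_next)
  CAp <- nerf_place_r(Cp, N1, CA1, g$b_ca_c, g$a_ca_c_n, omega_new)
  Np <- nerf_place_r(CAp, Cp, N1, g$b_n_ca, g$a_n_ca_c, psi_new)
  Op <- nerf_place_r(Cp, N1, CA1, g$b_c_o, 123.2, 0)
  m <- rbind(N = Np, CA = CAp, C = Cp, O = Op)
  res <- list(code = code, atoms = m)
  res <- build_side_chain(res, chis)
  pose$residues <- c(list(res), pose$residues)
  pose$chain <- c(pose$chain[1], pose$chain)
  pose
}

## (Re)build a residue's side chain (CB onward) from its template's
## internal coordinates given backbone N/CA/C(/O) coordinates.
build_side_chain <- function(res, chis = NULL) {
  tpl <- get_template(res$code)
  bb <- res$atoms[intersect(c("N", "CA", "C", "O"), rownames(res$atoms)), ,
                  drop = FALSE]
  coords <- bb
  side <- tpl$atoms[!tpl$atoms$name %in% c("N", "CA", "C", "O"), ,
                    drop = FALSE]
  if (nrow(side) == 0) { res$atoms <- coords; return(res) }
  if (is.null(chis)) {
    chis <- if (tpl$n_chi > 0) tpl$rotamers[1, ] else numeric(0)
  }
  chis <- rep_len(chis, max(tpl$n_chi, length(chis)))
  for (k in seq_len(nrow(side))) {
    a <- side[k, ]
    p <- parse_torsion_expr(a$torsion)
    tor <- switch(p$kind,
                  fixed = p$offset,
                  chi = chis[p$idx] + p$offset,
                  stop("side-chain atom ", a$name,
                       " uses backbone torsion ", a$torsion))
    X <- nerf_place_r(coords[a$ref1, ], coords[a$ref2, ], coords[a$ref3, ],
                      a$bond, a$angle, tor)
    coords <- rbind(coords, X)
    rownames(coords)[nrow(coords)] <- a$name
  }
  res$atoms <- coords
  res
}
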