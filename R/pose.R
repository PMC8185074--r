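## The Pose: an ordered list of polymer residues (possibly head-to-tail
## cyclic) plus hetero entities (catalytic zinc, structural waters).
## Residue numbering is 1-based and contiguous per chain; coordinates in
## Angstrom.

VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, ZN = 1.39, H = 1.0)

#' Construct a Pose
#'
#' @param residues list of residues, each `list(code=, atoms=)` where
#'   `atoms` is an n x 3 coordinate matrix with atom-name rownames
#' @param chain chain id per residue (recycled)
#' @param cyclic head-to-tail amide between last C and first N
#' @param zinc list of zinc sites `list(position=, target=)`
#' @param waters list with `positions` (n x 3 matrix) and `structural`
#'   (logical)
#' @return a `Pose`
#' @export
new_pose <- function(residues = list(), chain = "P", cyclic = FALSE,
                     zinc = list(), waters = NULL) {
  if (is.null(waters))
    waters <- list(positions = matrix(numeric(0), 0, 3),
                   structural = logical(0))
  chain <- rep_len(chain, length(residues))
  structure(list(residues = residues, chain = chain, cyclic = cyclic,
                 zinc = zinc, waters = waters),
            class = "Pose")
}

#' Number of polymer residues in a pose
#' @param pose a `Pose`
#' @return integer
#' @export
pose_size <- function(pose) length(pose$residues)

#' Chain ids that are head-to-tail cyclic
#'
#' The `cyclic` slot is either logical (TRUE = every chain cyclic, the
#' common case for a lone macrocycle) or a character vector of chain ids
#' (a cyclic peptide bound to a linear receptor).
#'
#' @param pose a `Pose`
#' @return character vector (possibly empty)
#' @export
cyclic_chains <- function(pose) {
  if (is.character(pose$cyclic)) return(intersect(pose$cyclic, pose$chain))
  if (isTRUE(pose$cyclic)) return(unique(pose$chain))
  character(0)
}

#' @export
print.Pose <- function(x, ...) {
  cyc <- cyclic_chains(x)
  cat(sprintf("Pose: %d residues (%s)%s, %d zinc, %d waters\n",
              pose_size(x),
              paste(unique(x$chain), collapse = ","),
              if (length(cyc)) paste0(", cyclic [",
                                      paste(cyc, collapse = ","), "]") else "",
              length(x$zinc), nrow(x$waters$positions)))
  invisible(x)
}

#' Residue sequence of a pose
#' @param pose a `Pose`
#' @param chain optional chain id filter
#' @return character vector of 3-letter codes
#' @export
pose_sequence <- function(pose, chain = NULL) {
  sel <- if (is.null(chain)) seq_along(pose$residues)
         else which(pose$chain == chain)
  vapply(pose$residues[sel], `[[`, character(1), "code")
}

#' Coordinates of one named atom
#' @param pose a `Pose`
#' @param resno residue index (pose-wide)
#' @param name atom name
#' @return numeric 3-vector
#' @export
get_atom <- function(pose, resno, name) {
  atoms <- pose$residues[[resno]]$atoms
  if (!name %in% rownames(atoms))
    stop("residue ", resno, " has no atom ", name)
  as.numeric(atoms[name, ])
}

#' Flat atom table of a pose
#'
#' One row per heavy atom, including water oxygens and zinc when
#' `include_het`. Columns: resno (0 for het), chain, code, name, element,
#' role, radius, charge, x, y, z.
#'
#' @param pose a `Pose`
#' @param include_het include waters ("W" chain) and zinc ("Z" chain)
#' @return data.frame
#' @export
pose_atoms <- function(pose, include_het = TRUE) {
  rows <- vector("list", length(pose$residues) + 2)
  for (i in seq_along(pose$residues)) {
    res <- pose$residues[[i]]
    tpl <- get_template(res$code)
    nm <- rownames(res$atoms)
    meta <- tpl$atoms[match(nm, tpl$atoms$name), ]
    rows[[i]] <- data.frame(
      resno = i, chain = pose$chain[i], code = res$code, name = nm,
      element = meta$element, role = meta$role,
      x = res$atoms[, 1], y = res$atoms[, 2], z = res$atoms[, 3],
      stringsAsFactors = FALSE)
  }
  if (include_het && nrow(pose$waters$positions) > 0) {
    w <- pose$waters$positions
    rows[[length(pose$residues) + 1]] <- data.frame(
      resno = 0, chain = "W", code = "HOH", name = "O", element = "O",
      role = "both", x = w[, 1], y = w[, 2], z = w[, 3],
      stringsAsFactors = FALSE)
  }
  if (include_het && length(pose$zinc) > 0) {
    zn <- do.call(rbind, lapply(pose$zinc, `[[`, "position"))
    rows[[length(pose$residues) + 2]] <- data.frame(
      resno = 0, chain = "Z", code = "ZN", name = "ZN", element = "ZN",
      role = "none", x = zn[, 1], y = zn[, 2], z = zn[, 3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out$radius <- unname(VDW_RADII[out$element])
  out$charge <- atom_charges(out$code, out$name, out$role)
  out
}

## simple rule-based partial/formal charges for the screened-Coulomb term
atom_charges <- function(code, name, role) {
  q <- ifelse(role == "donor", 0.2, ifelse(role == "acceptor", -0.2, 0))
  q[code %in% c("ARG", "DAR") & name %in% c("NH1", "NH2")] <- 0.5
  q[code %in% c("LYS", "DLY") & name == "NZ"] <- 1.0
  q[code %in% c("ASP", "DAS") & name %in% c("OD1", "OD2")] <- -0.5
  q[code %in% c("GLU", "DGL") & name %in% c("OE1", "OE2")] <- -0.5
  q[code == "ZN"] <- 0  # zinc handled by its coordination restraint
  q
}

#' Coordinate matrix of a flat atom table
#' @param atoms_df data.frame from [pose_atoms()]
#' @return n x 3 numeric matrix
#' @export
coords_matrix <- function(atoms_df) {
  as.matrix(atoms_df[, c("x", "y", "z")])
}

#' Subset a pose to one or more chains
#' @param pose a `Pose`
#' @param chains chain ids to keep
#' @param keep_het keep waters and zinc sites
#' @return a `Pose`
#' @export
pose_chain_subset <- function(pose, chains, keep_het = TRUE) {
  sel <- pose$chain %in% chains
  new_pose(pose$residues[sel], pose$chain[sel],
           cyclic = intersect(cyclic_chains(pose), chains),
           zinc = if (keep_het) pose$zinc else list(),
           waters = if (keep_het) pose$waters
                    else list(positions = matrix(numeric(0), 0, 3),
                              structural = logical(0)))
}

#' Merge two poses (e.g. receptor and peptide) into one complex
#' @param a,b `Pose` objects with disjoint chain ids
#' @return combined `Pose`
#' @export
pose_merge <- function(a, b) {
  new_pose(c(a$residues, b$residues), c(a$chain, b$chain),
           cyclic = union(cyclic_chains(a), cyclic_chains(b)),
           zinc = c(a$zinc, b$zinc),
           waters = list(
             positions = rbind(a$waters$positions, b$waters$positions),
             structural = c(a$waters$structural, b$waters$structural)))
}

## Bonded atom pairs (global flat-table indices), from template topology
## (each atom's first reference is its bonded parent), inter-residue
## peptide bonds, and the closure bond when cyclic.
pose_bond_pairs <- function(pose, atoms_df = NULL) {
  if (is.null(atoms_df)) atoms_df <- pose_atoms(pose, include_het = FALSE)
  key <- paste(atoms_df$resno, atoms_df$name)
  idx <- setNames(seq_len(nrow(atoms_df)), key)
  pairs <- list()
  for (i in seq_along(pose$residues)) {
    tpl <- get_template(pose$residues[[i]]$code)
    for (k in seq_len(nrow(tpl$atoms))) {
      ref <- tpl$atoms$ref1[k]
      if (startsWith(ref, "-")) {
        prev <- i - 1
        if (prev < 1 || pose$chain[prev] != pose$chain[i]) next
        j <- idx[paste(prev, substring(ref, 2))]
      } else j <- idx[paste(i, ref)]
      a <- idx[paste(i, tpl$atoms$name[k])]
      if (!is.na(j) && !is.na(a)) pairs[[length(pairs) + 1]] <- c(j, a)
    }
  }
  for (c0 in cyclic_chains(pose)) {
    members <- which(pose$chain == c0)
    if (length(members) < 2) next
    a <- idx[paste(max(members), "C")]
    b <- idx[paste(min(members), "N")]
    if (!is.na(a) && !is.na(b)) pairs[[length(pairs) + 1]] <- c(a, b)
  }
  if (length(pairs) == 0) return(matrix(integer(0), 2, 0))
  t(do.call(rbind, pairs))
}

#' Atom pairs excluded from nonbonded terms
#'
#' Pairs within `sep` bonds of each other (default 3: excludes 1-2,
#' 1-3 and 1-4 interactions).
#'
#' @param pose a `Pose`
#' @param atoms_df optional flat atom table (polymer atoms only)
#' @param sep bond-separation threshold
#' @return 2 x m integer matrix of flat-table atom indices
#' @export
bonded_exclusions <- function(pose, atoms_df = NULL, sep = 3) {
  if (is.null(atoms_df)) atoms_df <- pose_atoms(pose, include_het = FALSE)
  n <- nrow(atoms_df)
  bp <- pose_bond_pairs(pose, atoms_df)
  adj <- vector("list", n)
  for (j in seq_len(ncol(bp))) {
    a <- bp[1, j]; b <- bp[2, j]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- list()
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    for (d in seq_len(sep)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- d
      frontier <- nxt
    }
    reach <- which(!is.na(dist) & seq_len(n) > s)
    if (length(reach))
      out[[length(out) + 1]] <- rbind(s, reach)
  }
  if (length(out) == 0) return(matrix(integer(0), 2, 0))
  do.call(cbind, out)
}

#' Through-bond path length between two atoms of one residue
#'
#' Breadth-first search over the residue's template bond graph; used for
#' template topology checks (e.g. the anchor's CA-to-thiol span).
#'
#' @param template a `ResidueTemplate`
#' @param from,to atom names
#' @return integer bond count (NA if disconnected)
#' @export
bond_path_length <- function(template, from, to) {
  nm <- template$atoms$name
  adj <- vector("list", length(nm))
  names(adj) <- nm
  for (k in seq_len(nrow(template$atoms))) {
    ref <- template$atoms$ref1[k]
    if (ref %in% nm) {
      adj[[ref]] <- c(adj[[ref]], nm[k])
      adj[[nm[k]]] <- c(adj[[nm[k]]], ref)
    }
  }
  dist <- setNames(rep(NA_integer_, length(nm)), nm)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), names(dist)[!is.na(dist)])
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1]] + 1L
    ## BFS layer by layer: all frontier nodes share a distance
    frontier <- nxt
  }
  unname(dist[to])
}
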