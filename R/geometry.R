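## Torsion math, superposition, chirality and torsion-bin utilities.
## Conventions: coordinates in Angstrom, torsions in degrees in (-180, 180],
## IUPAC dihedral sign (trans = 180).

#' Wrap an angle into (-180, 180]
#' @param x angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x <= -180] <- x[x <= -180] + 360
  ## map exact -180 to +180 to honor the half-open convention
  x[abs(x + 180) < 1e-12] <- 180
  x
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion p1-p2-p3-p4 in degrees, IUPAC sign convention
#' (looking down p2->p3, clockwise rotation of p4 relative to p1 is
#' positive; trans = 180).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return angle in degrees in (-180, 180]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9)
    stop("dihedral: consecutive points coincide")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("dihedral: collinear points give an undefined torsion")
  dihedral_cpp(p1, p2, p3, p4)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at p2 formed by p1-p2-p3, in degrees
#' @param p1,p2,p3 numeric 3-vectors
#' @return angle in degrees
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the rigid transform minimizing the RMSD of `mobile` onto `target`
#' (rows are corresponding points).
#'
#' @param mobile,target numeric matrices, n x 3, n >= 3
#' @return list with `rotation` (3x3, det +1), `translation` (3-vector such
#'   that `mobile %*% t(rotation) + translation` superposes), and `rmsd`
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("superpose: point sets must have equal cardinality")
  if (nrow(mobile) < 3) stop("superpose: need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("superpose: degenerate (rank-deficient) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # target ~ mobile %*% t(R) + trans
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = as.numeric(ct - cm %*% t(R)), rmsd = rmsd)
}

#' Apply a rigid transform from [superpose()] to coordinates
#' @param coords n x 3 matrix
#' @param tr list with `rotation` and `translation`
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(coords, tr) {
  sweep(as.matrix(coords) %*% t(tr$rotation), 2, tr$translation, `+`)
}

#' Backbone chirality implied by a phi torsion
#'
#' Scanned and designed positions follow the rule that negative phi
#' backbones take L residues and positive phi backbones take D residues.
#' The tie at phi = 0 (or 180) resolves to L.
#'
#' @param phi torsion in degrees in (-180, 180]
#' @return "L" or "D"
#' @export
chirality_for_phi <- function(phi) {
  ifelse(phi > 0 & phi < 180, "D", "L")
}

#' Bin a (phi, psi) pair on a square torsion grid
#'
#' Bins are half-open `[lo, lo + width)` starting at -180; a 30 degree
#' width gives 12 x 12 = 144 bins.
#'
#' @param phi,psi torsions in degrees
#' @param width bin width in degrees; must divide 360
#' @return list with integer `phi_bin`, `psi_bin` (0-based), `width`
#' @export
bin_torsions <- function(phi, psi, width = 30) {
  if (360 %% width != 0) stop("bin width must divide 360")
  idx <- function(x) {
    x <- (x + 180) %% 360   # in [0, 360)
    as.integer(floor(x / width)) %% as.integer(360 / width)
  }
  list(phi_bin = idx(phi), psi_bin = idx(psi), width = width)
}

#' Centers of all torsion bins of a given width
#' @param width bin width in degrees
#' @return data.frame with phi_bin, psi_bin, phi, psi (bin centers)
#' @export
torsion_bin_centers <- function(width = 30) {
  if (360 %% width != 0) stop("bin width must divide 360")
  nb <- 360 / width
  g <- expand.grid(phi_bin = 0:(nb - 1), psi_bin = 0:(nb - 1))
  g$phi <- -180 + (g$phi_bin + 0.5) * width
  g$psi <- -180 + (g$psi_bin + 0.5) * width
  g
}
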