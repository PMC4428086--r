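# Low-level 3D geometry: internal-coordinate chain building (NeRF), dihedrals,
# rotations and least-squares superposition. Coordinates are plain numeric
# matrices (n x 3) in Angstrom throughout.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (need not be normalised).
#' @param theta angle in radians.
#' @return 3x3 orthonormal rotation matrix (determinant +1).
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  u <- unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Natural extension reference frame: place atom D given positions of A, B, C,
# the bond length C-D, bond angle B-C-D (deg) and dihedral A-B-C-D (deg).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed dihedral angle A-B-C-D in degrees, in (-180, 180].
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares fits `mobile` onto `fixed` and returns the rotation,
#' translation and the RMSD after fitting. Used for fibril congruence checks
#' and trajectory superposition; cross-checked against bio3d in the tests.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matching rows.
#' @return list with `rotation` (3x3), `translation` (length 3; apply as
#'   `coords %*% t(rotation) + translation`), `rmsd`, and `fitted` coordinates.
#' @keywords internal
kabsch_fit <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed))
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P %*% t(R)
  fitted <- sweep(fitted, 2, cf, `+`)
  list(rotation = R,
       translation = as.numeric(cf - cm %*% t(R)),
       rmsd = sqrt(mean(rowSums((fitted - fixed)^2))),
       fitted = fitted)
}

# RMSD without fitting.
raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
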