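# Small 3D geometry kernel: dihedrals, internal-coordinate atom placement
# (NeRF), rotations.  Angles are degrees at the interfaces, radians inside.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#' @param a,b Numeric length-3 vectors.
#' @return Angle in degrees in [0, 180].
#' @keywords internal
vangle <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-9 || nb < 1e-9) return(0) # degenerate: flagged 0 by convention
  rad2deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
}

#' Dihedral angle of four points
#'
#' Standard IUPAC convention, range (-180, 180].
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @return Angle in degrees, or NA if degenerate.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

# Place atom D given A, B, C and internal coordinates: |C-D| = bond,
# angle(B,C,D) = angle_deg, dihedral(A,B,C,D) = torsion_deg.
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- deg2rad(angle_deg); chi <- -deg2rad(torsion_deg)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          bond * sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix about an axis
#' @param axis Length-3 axis (normalized internally).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- vunit(axis); th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# uniform random unit vector (uses the active RNG stream)
random_unit_vector <- function() {
  v <- stats::rnorm(3)
  while (vnorm(v) < 1e-8) v <- stats::rnorm(3)
  vunit(v)
}

# rotate rows of an n x 3 matrix about an axis through `origin`
rotate_points <- function(xyz, origin, axis, angle_deg) {
  R <- rotation_about_axis(axis, angle_deg)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# best-fitting plane normal of a point set (smallest singular vector)
plane_normal <- function(xyz) {
  xyzc <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(xyzc)
  s$v[, 3]
}
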