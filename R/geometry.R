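# Vector geometry: dihedrals, bond angles, NeRF atom placement, rigid motions.
# All coordinates are plain numeric 3-vectors (or n x 3 matrices) in nm.

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vec_norm <- function(a) sqrt(sum(a * a))

vec_unit <- function(a) {
  n <- vec_norm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle of four points
#'
#' Signed torsion angle defined by points `p1-p2-p3-p4` about the
#' `p2-p3` axis, using the standard IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (nm; any consistent unit).
#' @return Angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  ang <- -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

# angle at vertex `b` between rays b->a and b->c, degrees
point_angle <- function(a, b, c) {
  u <- vec_unit(a - b)
  v <- vec_unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Natural extension reference frame: place atom D bonded to C, given
# positions A, B, C, the C-D bond length, the B-C-D angle (deg) and the
# A-B-C-D torsion (deg). Sign convention matches dihedral_angle().
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- vec_unit(c - b)
  n <- vec_unit(vec_cross(b - a, bc))
  p <- vec_cross(n, bc)
  d <- bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * p + sin(tor) * n))
  c + d
}

# Rotation matrix from an axis (3-vector) and angle in radians.
rotation_matrix <- function(axis, theta) {
  u <- vec_unit(axis)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# Apply rotation R about `center` then translation `shift` to an n x 3 matrix.
transform_coords <- function(xyz, rot = diag(3), center = c(0, 0, 0),
                             shift = c(0, 0, 0)) {
  sweep(sweep(xyz, 2L, center) %*% t(rot), 2L, center + shift, `+`)
}

# Rotation from a length-3 rotation vector (axis * angle in radians).
rotvec_matrix <- function(v) {
  th <- vec_norm(v)
  if (th < 1e-12) return(diag(3))
  rotation_matrix(v / th, th)
}

# Uniform random rotation matrix (via random unit quaternion).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vec_norm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}
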