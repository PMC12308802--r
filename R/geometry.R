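# Small 3D geometry kernel used throughout: vectors are length-3 numerics,
# point sets are n x 3 matrices. Angles are in degrees at the API surface.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vdist <- function(a, b) vnorm(a - b)

#' Angle at vertex b
#'
#' Returns the a-b-c angle in degrees.
#' @param a,b,c numeric length-3 coordinates (Angstrom).
#' @return angle in degrees in [0, 180].
#' @keywords internal
vangle <- function(a, b, c) {
  u <- unitv(a - b)
  w <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * w)))))
}

#' Dihedral angle a-b-c-d
#'
#' Signed torsion in degrees in (-180, 180], IUPAC sign convention.
#' @param a,b,c,d numeric length-3 coordinates.
#' @return dihedral in degrees.
#' @keywords internal
vdihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# cross product (kept local; avoids pulling a dependency for one primitive)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rotate points about an arbitrary axis
#'
#' Rodrigues rotation of one or more points about the axis through `origin`
#' with direction `axis`, by `theta` degrees (right-handed).
#'
#' @param pts numeric length-3 vector or n x 3 matrix.
#' @param origin point on the rotation axis.
#' @param axis axis direction (need not be unit length).
#' @param theta rotation angle, degrees.
#' @return rotated coordinates, same shape as `pts`.
#' @keywords internal
rotate_about_axis <- function(pts, origin, axis, theta) {
  single <- is.null(dim(pts))
  m <- if (single) matrix(pts, nrow = 1) else pts
  k <- unitv(axis)
  th <- deg2rad(theta)
  ct <- cos(th)
  st <- sin(th)
  out <- m
  for (i in seq_len(nrow(m))) {
    p <- m[i, ] - origin
    rot <- p * ct + pracma_cross(k, p) * st + k * sum(k * p) * (1 - ct)
    out[i, ] <- rot + origin
  }
  if (single) out[1, ] else out
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions a-b-c, returns the point d with bond
#' length |c-d| = `bond`, angle b-c-d = `angle` and dihedral a-b-c-d =
#' `dihedral` (standard natural-extension construction).
#'
#' @param a,b,c reference coordinates.
#' @param bond Angstrom; @param angle,dihedral degrees.
#' @return numeric length-3 position of the new atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  ang <- deg2rad(180 - angle)
  dih <- deg2rad(dihedral)
  d2 <- c(bond * cos(ang),
          bond * sin(ang) * cos(dih),
          -bond * sin(ang) * sin(dih))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}
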