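# Internal vector helpers shared by the geometry modules. All angles are in
# degrees at the API surface; radians internally.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Fold an angle into [0, 90] degrees
#'
#' Maps an angle `a` (degrees) to `min(a, 180 - a)`. Used for every
#' orientation descriptor because ring normals have no physical sign.
#'
#' @param a angle in degrees, in \[0, 180\].
#' @return angle in degrees in \[0, 90\].
#' @export
fold90 <- function(a) pmin(a, 180 - a)

# Unfolded angle between two vectors, degrees in [0, 180].
angle_deg <- function(u, v) {
  rad2deg(acos(clamp1(sum(u * v) / (vnorm(u) * vnorm(v)))))
}

# Rodrigues rotation matrix about unit axis by angle (radians).
rotation_about <- function(axis, theta) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotation matrix mapping unit vector `from` onto unit vector `to`,
# deterministic for the antiparallel case.
rotation_align <- function(from, to) {
  f <- unitv(from); t <- unitv(to)
  c_ <- sum(f * t)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis orthogonal to f, deterministically
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(pracma_cross(f, ref))
    return(rotation_about(axis, pi))
  }
  axis <- pracma_cross(f, t)
  rotation_about(unitv(axis), acos(clamp1(c_)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Least-squares plane through points (n x 3 matrix). Returns list(centroid,
# normal, rmsd): normal is the singular direction of smallest variance.
fit_plane <- function(xyz) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) >= 3)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  dev <- as.vector(sweep(xyz, 2, ctr) %*% normal)
  list(centroid = ctr, normal = unitv(normal), rmsd = sqrt(mean(dev^2)))
}
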