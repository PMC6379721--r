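# Small 3-vector helpers used throughout the package. All angles in degrees
# unless a function name says otherwise; all lengths in nm.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the (not necessarily unit)
#' axis `axis`, right-handed.
#'
#' @param axis 3-vector rotation axis.
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle) {
  u <- unitv(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation matrix (used by tests and the relaxation jitter).
random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Signed angle (degrees, in [0, 360)) from a to b about axis, measuring only
# the components of a and b perpendicular to the axis.
signed_angle_about <- function(a, b, axis) {
  n <- unitv(axis)
  ap <- a - sum(a * n) * n
  bp <- b - sum(b * n) * n
  if (vnorm(ap) < 1e-12 || vnorm(bp) < 1e-12)
    stop("vector parallel to reference axis; dihedral undefined")
  ang <- rad2deg(atan2(sum(cross3(ap, bp) * n), sum(ap * bp)))
  ang %% 360
}

# Minimal circular difference a - b on [-180, 180).
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}

# Circular mean of angles in degrees, mapped to [0, 360).
circ_mean <- function(x) {
  r <- deg2rad(x)
  rad2deg(atan2(mean(sin(r)), mean(cos(r)))) %% 360
}

# Apply a rigid motion (rotation R then translation t) to an n x 3 matrix.
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

# Least-squares direction of a set of points (first principal axis),
# returned as a unit vector with arbitrary sign.
principal_axis <- function(points) {
  if (nrow(points) < 2) stop("need at least two points to fit a line")
  centered <- sweep(points, 2, colMeans(points))
  sv <- svd(centered, nu = 0, nv = 1)
  as.numeric(sv$v[, 1])
}
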