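# Rotation utilities. Lab frame: X anterior, Y up, Z subject-right.
# Angles cross the API in degrees; radians are internal only.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for the right-handed rotation by `angle_deg` degrees
#' about the (not necessarily unit) 3-vector `axis`.
#'
#' @param axis numeric length-3 axis of rotation.
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' rot_about(c(0, 0, 1), 90)
rot_about <- function(axis, angle_deg) {
  a <- unit3(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose / decompose the flexion-adduction-rotation (Z-X-Y) sequence
#'
#' `euler_zxy()` builds the rotation `Rz(a) %*% Rx(b) %*% Ry(c)` from the
#' mobile Z-X'-Y'' (flexion, adduction, internal-rotation) angle triplet;
#' `decompose_zxy()` inverts it. This is the floating-axis joint coordinate
#' system used for the hip and knee: the flexion axis is fixed in the
#' proximal segment, the rotation axis in the distal segment, and the
#' adduction axis floats between them.
#'
#' @param angles_deg numeric length-3 angles (flexion, adduction, rotation)
#'   in degrees.
#' @param R a 3x3 rotation matrix.
#' @return `euler_zxy()` a 3x3 rotation matrix; `decompose_zxy()` the angle
#'   triplet in degrees with a `gimbal` attribute flagging |adduction|
#'   within 1 degree of 90.
#' @export
euler_zxy <- function(angles_deg) {
  rot_about(c(0, 0, 1), angles_deg[1]) %*%
    rot_about(c(1, 0, 0), angles_deg[2]) %*%
    rot_about(c(0, 1, 0), angles_deg[3])
}

#' @rdname euler_zxy
#' @export
decompose_zxy <- function(R) {
  beta <- asin(max(-1, min(1, R[3, 2])))
  alpha <- atan2(-R[1, 2], R[2, 2])
  gamma <- atan2(-R[3, 1], R[3, 3])
  out <- rad2deg(c(alpha, beta, gamma))
  names(out) <- c("flexion", "adduction", "rotation")
  attr(out, "gimbal") <- abs(abs(out[2]) - 90) < 1
  out
}

# Angle of a rotation known to be about a given axis.
angle_about_axis <- function(R, axis) {
  a <- unit3(axis)
  # any vector perpendicular to the axis
  e <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- unit3(e - sum(e * a) * a)
  q <- as.vector(R %*% p)
  q <- q - sum(q * a) * a
  rad2deg(atan2(sum(cross3(p, q) * a), sum(p * q)))
}

# Decompose R (assumed to lie on the two-axis manifold) as
# R = rot_about(a1, th1) %*% rot_about(a2, th2), a1 fixed in the proximal
# frame, a2 fixed in the distal frame -- the universal-joint analogue of the
# floating-axis sequence. Returns degrees c(th1, th2).
decompose_two_axis <- function(R, a1, a2) {
  a1 <- unit3(a1); a2 <- unit3(a2)
  b <- as.vector(crossprod(R, a1))          # t(R) %*% a1
  p1 <- a1 - sum(a1 * a2) * a2
  pb <- b - sum(b * a2) * a2
  if (sqrt(sum(p1^2)) < 1e-12 || sqrt(sum(pb^2)) < 1e-12)
    stop("degenerate two-axis decomposition: joint axes nearly parallel")
  th2 <- -rad2deg(atan2(sum(cross3(p1, pb) * a2), sum(p1 * pb)))
  R1 <- R %*% t(rot_about(a2, th2))
  th1 <- angle_about_axis(R1, a1)
  c(th1, th2)
}
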