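# Small vector-geometry kernels shared across the package.
# All angles at the package surface are degrees; radians appear only
# transiently inside trigonometric calls.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.cross3 <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

.norm3 <- function(x) sqrt(sum(x^2))

.unit3 <- function(x) {
  n <- .norm3(x)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  x / n
}

#' Wrap angles to a half-open interval
#'
#' @param x angles in degrees.
#' @param lower lower bound of the target interval; the interval is
#'   `[lower, lower + 360)`.
#' @return wrapped angles in degrees.
#' @keywords internal
.wrapAngle <- function(x, lower = -180) {
  ((x - lower) %% 360) + lower
}

#' Circular mean of angles in degrees
#' @keywords internal
.circMean <- function(x) {
  r <- .deg2rad(x)
  .wrapAngle(.rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

# Dihedral angle of four points, degrees in [-180, 180).
# Praxeolitic formulation: numerically stable near 0 and 180.
.dihedral4 <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- .unit3(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  ang <- .rad2deg(atan2(sum(.cross3(b1, v) * w), sum(v * w)))
  .wrapAngle(ang)
}

# Place atom D given A-B-C, bond length |C-D|, bond angle B-C-D (deg) and
# dihedral A-B-C-D (deg); standard internal-coordinate (NeRF) construction.
.placeAtom <- function(A, B, C, len, ang, dih) {
  ang <- .deg2rad(ang)
  dih <- .deg2rad(dih)
  bc <- .unit3(C - B)
  n <- .unit3(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- len * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rigid transform `x -> R x + t` that best maps the rows
#' of `from` onto the rows of `to` in the least-squares sense.
#'
#' @param from,to n x 3 coordinate matrices with matched rows.
#' @return list with rotation matrix `R` (3 x 3, det +1) and translation `t`.
#' @export
kabschTransform <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  stopifnot(ncol(from) == 3, ncol(to) == 3, nrow(from) == nrow(to),
            nrow(from) >= 3)
  cf <- colMeans(from); ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(ct - R %*% cf))
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix or length-3 vector.
#' @param transform list with `R` and `t` as returned by [kabschTransform()].
#' @return transformed coordinates, same shape as input.
#' @export
applyTransform <- function(xyz, transform) {
  if (is.null(dim(xyz))) {
    as.numeric(transform$R %*% xyz + transform$t)
  } else {
    sweep(as.matrix(xyz) %*% t(transform$R), 2, transform$t, "+")
  }
}

# Rotation matrix for angle deg about unit axis u (Rodrigues).
.rotationAboutAxis <- function(u, deg) {
  u <- .unit3(u)
  th <- .deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
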