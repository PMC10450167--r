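#' @title Rigid-body geometry primitives
#' @description Small set of vector/rotation utilities used by the fragment
#'   matching, descriptor extraction and duplex generation code. All
#'   coordinates are plain n x 3 numeric matrices in Angstrom.
#' @name geometry
#' @keywords internal
NULL

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from axis-angle (Rodrigues)
#' @param axis length-3 axis (need not be unit)
#' @param angle rotation angle in radians
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotvec_to_matrix <- function(rv) {
  th <- vnorm(rv)
  if (th < 1e-12) return(diag(3))
  rotation_about_axis(rv, th)
}

matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-9) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-9) {
    # 180 degree rotation: axis from R + I columns
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    ax <- M[, j]
  }
  unit(ax) * th
}

#' Rigid transform as a list(R = 3x3, t = length-3)
#' @keywords internal
rigid <- function(R = diag(3), t = c(0, 0, 0)) list(R = R, t = t)

apply_rigid <- function(tr, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  sweep(xyz %*% t(tr$R), 2, tr$t, "+")
}

compose_rigid <- function(a, b) {
  # (a o b)(x) = a(b(x))
  rigid(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t) + a$t)
}

invert_rigid <- function(tr) {
  Rt <- t(tr$R)
  rigid(R = Rt, t = as.numeric(-Rt %*% tr$t))
}

random_rigid <- function() {
  rv <- stats::rnorm(3)
  rv <- unit(rv) * stats::runif(1, 0, pi)
  rigid(R = rotvec_to_matrix(rv), t = stats::rnorm(3, sd = 10))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum || R x_i + t - y_i ||^2` over paired point sets.
#'
#' @param x n x 3 matrix of moving points
#' @param y n x 3 matrix of fixed (target) points
#' @return list with `R`, `t` and the residual `rmsd` (Angstrom)
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  H <- t(xc) %*% yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tvec <- cy - as.numeric(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  list(R = R, t = tvec, rmsd = rmsd)
}

#' RMSD between two paired coordinate sets after optimal superposition
#' @param x,y n x 3 matrices
#' @return numeric RMSD in Angstrom
#' @export
superposed_rmsd <- function(x, y) kabsch(x, y)$rmsd

#' Best-fit plane through points
#' @param xyz n x 3 matrix, n >= 3
#' @return list(center, normal); errors if the points are collinear
#' @keywords internal
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  s <- svd(xc)
  # collinear (or coincident) points: second singular value ~ 0
  if (s$d[2] < 1e-6 * max(s$d[1], 1e-6)) {
    stop("degenerate (collinear) points: no unique best-fitting plane")
  }
  list(center = ctr, normal = s$v[, 3])
}

deg2rad <- function(x) x * pi / 180

#' Dihedral angle (radians) defined by four points
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}
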