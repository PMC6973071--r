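# Internal vector geometry. All angles in degrees, all distances in Angstrom.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))
.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}
.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap into (-180, 180]
.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
# wrap into [0, 360)
.wrap360 <- function(x) x %% 360

# smallest absolute angular difference (degrees)
.angdiff <- function(a, b) {
  d <- abs(.wrap180(a - b))
  d
}

#' Signed dihedral angle between four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, the angle is positive when
#' the far bond (`p3`->`p4`) is rotated clockwise from the near bond
#' (`p2`->`p1`).
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian coordinates (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  .wrap180(.rad2deg(atan2(y, x)))
}

# angle p1-p2-p3 in degrees
.angle3 <- function(p1, p2, p3) {
  u <- .vunit(p1 - p2)
  v <- .vunit(p3 - p2)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# rotation matrix about unit axis by theta degrees (Rodrigues)
.rotmat <- function(axis, theta) {
  u <- .vunit(axis)
  th <- .deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# rotation mapping unit vector a onto unit vector b
.rot_between <- function(a, b) {
  a <- .vunit(a); b <- .vunit(b)
  v <- .vcross(a, b)
  c_ <- sum(a * b)
  if (.vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .vunit(.vcross(a, p))
    return(.rotmat(ax, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# least-squares plane through rows of X: list(centroid, normal, rmax)
.plane_fit <- function(X) {
  ctr <- colMeans(X)
  Y <- sweep(X, 2, ctr)
  sv <- svd(Y)
  n <- sv$v[, 3]
  res <- as.vector(Y %*% n)
  list(centroid = ctr, normal = n, residuals = res, max_residual = max(abs(res)))
}

# place atom D given positions A,B,C, bond |CD|, angle B-C-D and torsion A-B-C-D
# (standard internal-coordinate / NeRF construction)
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- .deg2rad(180 - angle)
  ph <- .deg2rad(-torsion)
  d2 <- c(bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  M <- cbind(bc, m, n)
  as.vector(M %*% d2) + c
}

# Kabsch: optimal proper rotation R and translation t minimizing |A R' + t - B|
# (A, B: n x 3 matched coordinate matrices; returns mapping of A onto B)
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - B0)^2)))
  t_ <- cb - as.vector(R %*% ca)
  list(rotation = R, translation = t_, rmsd = rmsd)
}
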