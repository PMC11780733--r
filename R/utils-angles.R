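#' Wrap angles to a canonical range
#'
#' `wrap180()` maps angles to \eqn{[-180, 180)} degrees, the range used for raw
#' torsion output; `wrap360()` maps to \eqn{[0, 360)}, the range used for
#' backbone dihedral reporting. Wrapping is always explicit in this package:
#' no function silently re-wraps its input.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped.
#' @export
#' @examples
#' wrap180(c(180, 360, -190))  # -180, 0, 170
#' wrap360(c(-10, 370))        # 350, 10
wrap180 <- function(x) {
  ((x + 180) %% 360) - 180
}

#' @rdname wrap180
#' @export
wrap360 <- function(x) {
  x %% 360
}

#' Shortest signed angular difference a - b in degrees, in [-180, 180).
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
angle_diff <- function(a, b) {
  wrap180(a - b)
}

#' Circular mean of angles in degrees
#'
#' Mean direction of a set of angles, reported in \eqn{[0, 360)}. Used for
#' averaging backbone dihedrals, where arithmetic means are meaningless across
#' the wrap point.
#'
#' @param x angles in degrees; `NA` values are dropped.
#' @return mean direction in degrees, or `NA` if no finite values.
#' @export
circular_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  m <- wrap360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
  if (360 - m < 1e-9) 0 else m
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

#' Signed dihedral angle from four points
#'
#' Standard four-atom torsion with the IUPAC sign convention: looking from the
#' second to the third point, a clockwise rotation of the 1-2 bond onto the
#' 3-4 bond is positive. The value is reported in \eqn{[-180, 180)}; an exact
#' trans arrangement is reported as -180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (angstrom or any
#'   consistent unit; only directions matter).
#' @return signed angle in degrees in \eqn{[-180, 180)}.
#' @export
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # ~ 0 (cis)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate geometry: three collinear points in dihedral")
  }
  b2u <- b2 / vnorm(b2)
  ang <- rad2deg(atan2(sum(cross3(n1, n2) * b2u), sum(n1 * n2)))
  wrap180(ang)
}

## Rodrigues rotation matrix about unit axis u by theta degrees.
rotation_matrix <- function(u, theta_deg) {
  u <- unitv(u)
  t <- deg2rad(theta_deg)
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

## Kabsch superposition: rotation R and translation t minimizing
## ||R s_i + t - x_i||^2. Returns list(R, t, rmsd).
kabsch <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 3, ncol(dst) == 3)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  A <- sweep(src, 2, cs)
  B <- sweep(dst, 2, cd)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cd - as.vector(R %*% cs)
  fit <- sweep(src %*% t(R), 2, tvec, "+")
  list(R = R, t = tvec, rmsd = sqrt(mean(rowSums((fit - dst)^2))))
}

## Place a new atom D given three atoms A-B-C, bond length |C-D|, angle B-C-D
## (degrees) and torsion A-B-C-D (degrees). Natural-extension construction.
nerf_place <- function(a, b, c, length, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.vector(M %*% d2) + c
}

## Two unit directions completing an approximately tetrahedral center whose
## two known substituent directions (unit vectors from the center) are d1, d2.
## Both returned vectors make the same angle theta with d1 and d2.
tetrahedral_directions <- function(d1, d2, theta_deg = 109.47) {
  ct <- cos(deg2rad(theta_deg))
  c12 <- sum(d1 * d2)
  a <- ct / (1 + c12)
  vp <- a * (d1 + d2)
  w <- cross3(d1, d2)
  w2 <- sum(w * w)
  rem <- 1 - sum(vp * vp)
  if (rem < 0 || w2 < 1e-12) stop("degenerate substituent directions")
  cc <- sqrt(rem / w2)
  list(plus = vp + cc * w, minus = vp - cc * w)
}

pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}
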