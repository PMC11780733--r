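# Independent oracles used across the suite. Each is coded from a different
# formulation than the implementation it checks.

# Dihedral via the two-plane normal-vector formula: angle between the plane
# normals with the sign taken from the scalar triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  n1 <- pracma_cross(p2 - p1, p3 - p2)
  n2 <- pracma_cross(p3 - p2, p4 - p3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(pracma_cross(n1, n2) * (p3 - p2)) < 0) ang <- -ang
  if (ang >= 180) ang <- ang - 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Term-by-term AMBER dihedral sum, written as an explicit loop.
oracle_dihedral_energy <- function(tt, phi) {
  total <- 0
  for (tm in tt$terms) {
    total <- total +
      tm$half_barrier / tm$divider *
      (1 + cos((tm$periodicity * phi - tm$phase) * pi / 180))
  }
  total
}

# Brute-force interval test for north classification.
oracle_is_north <- function(P) {
  w <- P %% 360
  (w >= 0 & w < 90) | (w > 270 & w < 360)
}

# Probability mass of a wrapped-normal mixture in [lo, hi) degrees.
oracle_mixture_bin_prob <- function(lo, hi, means, sds, weights) {
  total <- 0
  for (k in -2:2) {
    for (j in seq_along(means)) {
      total <- total + weights[j] *
        (stats::pnorm(hi + 360 * k, means[j], sds[j]) -
           stats::pnorm(lo + 360 * k, means[j], sds[j]))
    }
  }
  total
}

# Random orthonormal right-handed triad.
random_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-9) return(q)
  }
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(((a - b + 180) %% 360) - 180)), tol)
}
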