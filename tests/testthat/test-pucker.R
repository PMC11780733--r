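test_that("four-point dihedral reproduces planar limits and matches the normal-vector oracle", {
  # planar cis and trans arrangements
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
               -180)  # trans reported at the -180 boundary
  set.seed(42)
  for (i in 1:50) {
    pts <- matrix(rnorm(12), 4, 3)
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_angle_equal(got, want, tol = 1e-9)
  }
})

test_that("collinear points raise a degenerate-geometry error", {
  expect_error(
    dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear")
})

test_that("dihedral agrees with the bio3d torsion implementation", {
  set.seed(7)
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    ref <- bio3d::torsion.xyz(as.numeric(t(pts)), atm.inc = 4)
    expect_angle_equal(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                       ref[!is.na(ref)][1], tol = 1e-6)
  }
})

test_that("pseudorotation inverts the inverse map over the full phase grid", {
  for (P in scan_targets()) {
    for (tm in c(25, 35, 45)) {
      ps <- pseudorotation(ring_torsions_from_phase(P, tm))
      expect_angle_equal(ps$P, P, tol = 1e-9)
      expect_lt(abs(ps$tau_m - tm), 1e-9)
    }
  }
})

test_that("pseudorotation handles wrapping, the cos(P)=0 pole and planar rings", {
  ps <- pseudorotation(ring_torsions_from_phase(342, 35))
  expect_equal(ps$P, 342)            # not -18
  expect_equal(ps$pucker_class, "N")
  ps90 <- pseudorotation(ring_torsions_from_phase(90, 35))
  expect_angle_equal(ps90$P, 90, tol = 1e-9)  # nu2 = 0 here
  expect_lt(abs(ps90$tau_m - 35), 1e-9)
  expect_error(pseudorotation(rep(0, 5)), "planar")
  expect_error(pseudorotation(c(1, 2, 3)), "five")
})

test_that("north/south classification matches the brute-force interval test", {
  expect_equal(classify_pucker(18), "N")
  expect_equal(classify_pucker(150), "S")
  expect_equal(classify_pucker(90), "S")   # open-interval boundary
  expect_equal(classify_pucker(-90), "S")
  set.seed(11)
  P <- runif(10000, -720, 720)
  expect_identical(classify_pucker(P) == "N", unname(oracle_is_north(P)))
})

test_that("scan targets cover the pseudorotation cycle at the requested spacing", {
  expect_equal(scan_targets(), seq(0, 350, by = 10))
  expect_length(scan_targets(), 36)
  expect_equal(scan_targets(step = 90), c(0, 90, 180, 270))
  expect_error(scan_targets(step = 7), "does not divide")
  expect_error(scan_targets(step = -10), "positive")
})

test_that("scan constraints follow the inverse map and mirror across the cycle", {
  tm <- 35
  sc <- scan_constraints(scan_targets(), tm)
  # tau1 is nu1 of the inverse map
  for (i in seq_len(nrow(sc))) {
    nu <- ring_torsions_from_phase(sc$P[i], tm)
    expect_equal(sc$tau1[i], nu[2], tolerance = 1e-12)
  }
  # cosine antisymmetry: phases 180 apart give sign-mirrored tau1
  sc2 <- scan_constraints(c(30, 210), tm)
  expect_equal(sc2$tau1[1], -sc2$tau1[2], tolerance = 1e-9)
  # the tau1 zero crossing: nu1 = cos(P - 144) = 0 at P = 234
  expect_lt(abs(scan_constraints(234, tm)$tau1), 1e-9)
  # delta tracks nu3 by the constant exocyclic offset
  off <- scan_constraints(0, tm, delta_offset = 120)$delta -
    ring_torsions_from_phase(0, tm)[4]
  expect_equal(off, 120, tolerance = 1e-12)
})

test_that("angle wrap utilities use the documented canonical ranges", {
  expect_equal(wrap180(c(180, 360, -190, 170)), c(-180, 0, 170, 170))
  expect_equal(wrap360(c(-10, 370, 360)), c(350, 10, 0))
  expect_equal(angle_diff(10, 350), 20)
  expect_equal(angle_diff(350, 10), -20)
})
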