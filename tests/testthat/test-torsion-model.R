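planted_types <- function() {
  list(
    tau1 = torsion_type(c("C1", "C2", "C3", "C4"),
                        list(fourier_term(1, 1.2, 0),
                             fourier_term(2, -0.4, 180),
                             fourier_term(3, 0.8, 0))),
    delta = torsion_type(c("C5", "C4", "C3", "O3"),
                         list(fourier_term(1, 0.5, 180),
                              fourier_term(2, 0.3, 0),
                              fourier_term(3, -0.6, 180))))
}

planted_spec <- function(types = planted_types()) {
  skel <- lapply(types, function(tt) {
    tt$terms <- lapply(tt$terms, function(tm)
      fourier_term(tm$periodicity, 0, tm$phase, tm$divider))
    tt
  })
  fit_spec(skel, instances = as.list(stats::setNames(names(types),
                                                     names(types))))
}

test_that("dihedral energy matches closed forms and the term-by-term oracle", {
  t0 <- torsion_type(c("X", "X", "X", "X"), list(fourier_term(1, 0)))
  expect_equal(dihedral_energy(t0, seq(-180, 180, by = 5)),
               rep(0, 73))
  t2 <- torsion_type(c("X", "X", "X", "X"), list(fourier_term(2, 1.0, 180)))
  expect_equal(dihedral_energy(t2, 90), 2.0)
  tt <- planted_types()$tau1
  phi <- seq(-180, 179, by = 1)
  expect_equal(dihedral_energy(tt, phi),
               vapply(phi, oracle_dihedral_energy, numeric(1), tt = tt),
               tolerance = 1e-12)
})

test_that("dihedral energy is 360-degree periodic", {
  tt <- planted_types()$delta
  phi <- seq(0, 359, by = 7)
  expect_lt(max(abs(dihedral_energy(tt, phi) - dihedral_energy(tt, phi + 360))),
            1e-12)
})

test_that("CBS extrapolation has the right fixed point and recovers a planted limit", {
  expect_equal(cbs_extrapolate(5.5, 5.5), 5.5)  # equal energies: fixed point
  e_inf <- -3.21; A <- 7.5
  e3 <- e_inf + A / 3^3; e4 <- e_inf + A / 4^3
  expect_equal(cbs_extrapolate(e3, e4), e_inf, tolerance = 1e-10)
})

test_that("composite reference energy assembles its components", {
  # zero higher-order correction and no solvation: pure CBS sum
  out <- composite_reference_energy(
    e_hf_tz = -10, e_hf_qz = -10, e_corr_tz = -2, e_corr_qz = -2,
    e_ccsdt_dz = -5, e_mp2_dz = -5, g_solv = 0)
  expect_equal(as.numeric(out), -12)
  # planted inverse-power components recovered exactly
  hf_inf <- -100; corr_inf <- -8
  out2 <- composite_reference_energy(
    e_hf_tz = hf_inf + 2 / 27, e_hf_qz = hf_inf + 2 / 64,
    e_corr_tz = corr_inf + 5 / 27, e_corr_qz = corr_inf + 5 / 64,
    e_ccsdt_dz = -5.4, e_mp2_dz = -5.1, g_solv = -1.3)
  expect_equal(as.numeric(out2), hf_inf + corr_inf - 0.3 - 1.3,
               tolerance = 1e-10)
  expect_match(attr(out2, "scheme"), "X\\^-3")
  expect_equal(hartree_to_kcal(1), 627.509474)
})

test_that("fit target implements the dual-solvation residual with min-zero shift", {
  recs <- lapply(1:5, function(i)
    conformer_record(i * 10, c(t = 0), e_qm_gas = 2, g_solv_qm = -1,
                     e_mm_nontorsion = 0.5, g_solv_mm = 0.5))
  expect_equal(fit_target(recs), rep(0, 5))  # identical components: flat zero
  recs2 <- lapply(1:4, function(i)
    conformer_record(i, c(t = 0), e_qm_gas = c(3, 5, 4, 6)[i],
                     g_solv_qm = -1, e_mm_nontorsion = 1, g_solv_mm = 0.5))
  expect_equal(fit_target(recs2), c(0, 2, 1, 3))
  # gauge invariance: constant added to e_qm_gas shifts nothing after min-shift
  recs3 <- lapply(recs2, function(r) {
    r$e_qm_gas <- r$e_qm_gas + 7.3
    r
  })
  expect_equal(fit_target(recs3), fit_target(recs2))
})

test_that("noiseless planted scans are recovered exactly by the linear fit", {
  types <- planted_types()
  recs <- synth_scan(types, offset = 3.7)
  ft <- fit_fourier(recs, planted_spec(types))
  planted_amps <- unlist(lapply(types, function(tt)
    vapply(tt$terms, `[[`, numeric(1), "half_barrier")))
  got <- unlist(lapply(ft$types, function(tt)
    vapply(tt$terms, `[[`, numeric(1), "half_barrier")))
  expect_lt(max(abs(got - planted_amps)), 1e-8)
  expect_equal(ft$offset, 3.7, tolerance = 1e-8)
  expect_lt(ft$rmse, 1e-10)
})

test_that("a zero residual profile fits to all-zero amplitudes", {
  types <- planted_types()
  zero_types <- lapply(types, function(tt) {
    tt$terms <- lapply(tt$terms, function(tm)
      fourier_term(tm$periodicity, 0, tm$phase))
    tt
  })
  recs <- synth_scan(zero_types, offset = 0)
  ft <- fit_fourier(recs, planted_spec(types))
  expect_lt(max(abs(ft$coefficients)), 1e-10)
  expect_lt(ft$rmse, 1e-12)
})

test_that("fit is linear: fitting a sum of profiles gives the sum of fits", {
  types_a <- planted_types()
  types_b <- lapply(planted_types(), function(tt) {
    tt$terms <- lapply(tt$terms, function(tm)
      fourier_term(tm$periodicity, -0.5 * tm$half_barrier, tm$phase))
    tt
  })
  spec <- planted_spec(types_a)
  recs_a <- synth_scan(types_a, offset = 1)
  recs_b <- synth_scan(types_b, offset = 2)
  recs_sum <- synth_scan(types_a)  # same dihedral values; sum the energies
  for (i in seq_along(recs_sum)) {
    recs_sum[[i]]$e_qm_gas <- recs_a[[i]]$e_qm_gas + recs_b[[i]]$e_qm_gas
  }
  ca <- fit_fourier(recs_a, spec)$coefficients
  cb <- fit_fourier(recs_b, spec)$coefficients
  cs <- fit_fourier(recs_sum, spec)$coefficients
  expect_equal(cs, ca + cb, tolerance = 1e-8)
})

test_that("noisy planted scans are recovered without bias across seeds", {
  types <- planted_types()
  spec <- planted_spec(types)
  planted_amps <- unlist(lapply(types, function(tt)
    vapply(tt$terms, `[[`, numeric(1), "half_barrier")))
  n_seeds <- 200
  errs <- matrix(NA_real_, n_seeds, length(planted_amps))
  for (s in seq_len(n_seeds)) {
    recs <- synth_scan(types, offset = 1.5, noise_sd = 0.1, seed = s)
    ft <- fit_fourier(recs, spec)
    got <- unlist(lapply(ft$types, function(tt)
      vapply(tt$terms, `[[`, numeric(1), "half_barrier")))
    errs[s, ] <- got - planted_amps
  }
  mean_err <- colMeans(errs)
  mc_se <- apply(errs, 2, sd) / sqrt(n_seeds)
  expect_true(all(abs(mean_err) < 3 * mc_se))
  # and the per-fit standard errors are honest: errors scale like them
  recs <- synth_scan(types, offset = 1.5, noise_sd = 0.1, seed = 999)
  ft <- fit_fourier(recs, spec)
  expect_true(all(apply(errs, 2, sd) <
                    3 * ft$std_errors[seq_along(planted_amps)]))
})

test_that("rank-deficient designs are refused with the collinear columns named", {
  # duplicated periodicity/phase within one type makes identical columns
  tt <- torsion_type(c("A", "B", "C", "D"),
                     list(fourier_term(2, 0, 0), fourier_term(2, 0, 0)))
  spec <- fit_spec(list(tt), instances = list(x = "t1"))
  recs <- lapply(scan_targets(), function(P)
    conformer_record(P, c(t1 = scan_constraints(P, 35)$tau1, d = 0),
                     e_qm_gas = 1))
  expect_error(fit_fourier(recs, spec), "collinear")
})

test_that("phases outside 0/180 are rejected by the linear fit spec", {
  tt <- torsion_type(c("A", "B", "C", "D"), list(fourier_term(1, 0, 90)))
  expect_error(fit_spec(list(tt), instances = list(x = "t1")),
               "0 or 180")
})

test_that("empirical minimum adjustment moves the target window and pins the S minimum", {
  tt <- planted_types()$tau1
  expect_identical(empirical_adjustment(tt, delta_e = 0)$terms, tt$terms)
  adj <- empirical_adjustment(tt, center = 18, delta_e = -0.3)
  rep <- attr(adj, "report")
  expect_equal(rep$achieved_center, -0.3, tolerance = 0.03)
  expect_lt(abs(rep$achieved_s_min), 0.03)
  # direct re-evaluation along the scan mapping
  phi <- function(P) scan_constraints(P, 35)$tau1
  expect_equal(dihedral_energy(adj, phi(18)) - dihedral_energy(tt, phi(18)),
               -0.3, tolerance = 1e-9)
  # a single-term type cannot satisfy both constraints
  tt1 <- torsion_type(c("A", "B", "C", "D"), list(fourier_term(2, 0.5, 0)))
  expect_error(empirical_adjustment(tt1, center = 18, delta_e = -0.3),
               "infeasible")
})
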