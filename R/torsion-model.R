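#' Hartree to kcal/mol conversion
#'
#' All fitting machinery in this package works in kcal/mol and degrees;
#' electronic-structure energies supplied in hartree must be pre-converted.
#'
#' @param x energies in hartree.
#' @return energies in kcal/mol (1 hartree = 627.509474 kcal/mol).
#' @export
hartree_to_kcal <- function(x) x * 627.509474

#' Two-point complete-basis-set extrapolation
#'
#' Inverse-power extrapolation \eqn{E(X) = E_\infty + A X^{-p}} through two
#' cardinal numbers, by default (T, Q) = (3, 4) with the standard
#' \eqn{X^{-3}} exponent used for correlation energies:
#' \deqn{E_\infty = \frac{Y^p E_Y - X^p E_X}{Y^p - X^p}.}
#'
#' @param e_x,e_y energies at cardinal numbers `x` and `y` (kcal/mol).
#' @param x,y basis-set cardinal numbers (default 3 and 4).
#' @param power inverse-power exponent \eqn{p} (default 3).
#' @return extrapolated basis-set-limit energy.
#' @export
cbs_extrapolate <- function(e_x, e_y, x = 3, y = 4, power = 3) {
  stopifnot(x != y, power > 0)
  (y^power * e_y - x^power * e_x) / (y^power - x^power)
}

#' Composite solvation-corrected CCSD(T)/CBS reference energy
#'
#' Assembles the composite reference energy used as the fitting target for
#' torsion reparametrization: HF and MP2-correlation energies are separately
#' extrapolated to the basis-set limit from aug-cc-pVTZ/aug-cc-pVQZ values, a
#' higher-order correlation correction \eqn{E_{CCSD(T)} - E_{MP2}} evaluated
#' in aug-cc-pVDZ is added, and finally the conformer's solvation energy:
#' \deqn{E = E^{CBS}_{HF} + E^{CBS}_{corr}
#'        + (E^{DZ}_{CCSD(T)} - E^{DZ}_{MP2}) + G_{solv}.}
#' Both extrapolations use the two-point inverse-power scheme of
#' [cbs_extrapolate()]; the correlation exponent is the standard
#' \eqn{X^{-3}}, and the HF exponent defaults to the same power law for
#' consistency (configurable via `hf_power`, and recorded in the result's
#' attributes).
#'
#' @param e_hf_tz,e_hf_qz HF energies in the TZ and QZ basis (kcal/mol).
#' @param e_corr_tz,e_corr_qz correlation energies in the TZ and QZ basis.
#' @param e_ccsdt_dz,e_mp2_dz CCSD(T) and MP2 energies in the DZ basis.
#' @param g_solv conformer solvation energy (kcal/mol).
#' @param hf_power inverse-power exponent for the HF extrapolation.
#' @return composite energy in kcal/mol, with attribute `scheme` describing
#'   the extrapolation used.
#' @export
composite_reference_energy <- function(e_hf_tz, e_hf_qz, e_corr_tz, e_corr_qz,
                                       e_ccsdt_dz, e_mp2_dz, g_solv = 0,
                                       hf_power = 3) {
  e_hf <- cbs_extrapolate(e_hf_tz, e_hf_qz, power = hf_power)
  e_corr <- cbs_extrapolate(e_corr_tz, e_corr_qz, power = 3)
  out <- e_hf + e_corr + (e_ccsdt_dz - e_mp2_dz) + g_solv
  attr(out, "scheme") <- sprintf(
    "HF: two-point (3,4) X^-%g; corr: two-point (3,4) X^-3; + [CCSD(T)-MP2]/DZ + G_solv",
    hf_power)
  out
}

#' Conformer record for torsion fitting
#'
#' One point of a constrained conformer scan: the pseudorotation phase, the
#' values of every fitted dihedral instance, and the four energy components
#' entering the solvation-aware fit target.
#'
#' @param P pseudorotation phase of the scan point (degrees).
#' @param dihedral_values named numeric vector, one value (degrees) per
#'   dihedral instance id.
#' @param e_qm_gas QM gas-phase energy (kcal/mol).
#' @param g_solv_qm QM solvation energy (kcal/mol).
#' @param e_mm_nontorsion MM energy with the fitted torsions zeroed (kcal/mol).
#' @param g_solv_mm MM (Poisson-Boltzmann) solvation energy (kcal/mol).
#' @return list of class `"conformer_record"`.
#' @export
conformer_record <- function(P, dihedral_values, e_qm_gas, g_solv_qm = 0,
                             e_mm_nontorsion = 0, g_solv_mm = 0) {
  stopifnot(is.finite(P), length(dihedral_values) >= 1L,
            !is.null(names(dihedral_values)),
            all(is.finite(c(dihedral_values, e_qm_gas, g_solv_qm,
                            e_mm_nontorsion, g_solv_mm))))
  structure(list(P = P, dihedral_values = dihedral_values,
                 e_qm_gas = e_qm_gas, g_solv_qm = g_solv_qm,
                 e_mm_nontorsion = e_mm_nontorsion, g_solv_mm = g_solv_mm),
            class = "conformer_record")
}

#' Solvation-aware fitting target
#'
#' Per-conformer residual energy to be absorbed by the refitted torsion
#' terms. Solvation enters both the QM and MM sides, so subtracting the full
#' MM non-torsion energy (including its own solvation term) avoids double
#' counting:
#' \deqn{r_i = (E^{QM,gas}_i + G^{QM}_{solv,i})
#'           - (E^{MM,nontors}_i + G^{MM}_{solv,i}),}
#' shifted so the minimum is zero for reporting. The shift is immaterial for
#' fitting whenever the constant offset is included in the model.
#'
#' @param records list of [conformer_record()] objects.
#' @param shift logical; subtract the minimum (default `TRUE`).
#' @return numeric vector of residual energies (kcal/mol), one per record.
#' @export
fit_target <- function(records, shift = TRUE) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "conformer_record")))
  r <- vapply(records, function(rec) {
    (rec$e_qm_gas + rec$g_solv_qm) - (rec$e_mm_nontorsion + rec$g_solv_mm)
  }, numeric(1))
  if (shift) r <- r - min(r)
  r
}

#' Specification of a Fourier torsion refit
#'
#' Defines the linear model for [fit_fourier()]: which torsion types are
#' fitted, with which fixed periodicities and phases (phases restricted to 0
#' or 180 degrees so the model is linear in the half barriers), which
#' dihedral instances in the conformer records belong to each type, the
#' per-conformer weights, and whether a constant offset is fitted.
#'
#' @param types list of [torsion_type()] skeletons; their `half_barrier`
#'   values are ignored (amplitudes are free), periodicities, phases and
#'   dividers are fixed. All phases must be 0 or 180.
#' @param instances named list mapping each type (by position, names used for
#'   labels) to the character vector of dihedral-instance ids that share the
#'   type's parameters. Instance ids refer to names of `dihedral_values` in
#'   the conformer records.
#' @param weights optional nonnegative per-conformer weights (default equal).
#'   Boltzmann down-weighting of high-energy points can be requested instead
#'   via `boltzmann_T` (kelvin): weights \eqn{\exp(-r_i / RT)} computed from
#'   the shifted fit target.
#' @param include_offset fit a constant energy offset (default `TRUE`).
#' @param boltzmann_T optional temperature for Boltzmann weighting.
#' @return list of class `"fit_spec"`.
#' @export
fit_spec <- function(types, instances, weights = NULL, include_offset = TRUE,
                     boltzmann_T = NULL) {
  stopifnot(length(types) == length(instances),
            all(vapply(types, inherits, logical(1), "torsion_type")))
  phases <- unlist(lapply(types, function(tt)
    vapply(tt$terms, `[[`, numeric(1), "phase")))
  if (!all(phases %in% c(0, 180))) {
    stop("fit_spec phases must be 0 or 180 degrees (linear model)")
  }
  if (is.null(names(instances))) {
    names(instances) <- vapply(types, function(tt)
      paste(tt$atom_types, collapse = "-"), character(1))
  }
  structure(list(types = types, instances = instances, weights = weights,
                 include_offset = include_offset, boltzmann_T = boltzmann_T),
            class = "fit_spec")
}

#' Linear least-squares Fourier torsion refit
#'
#' Fits the half barriers \eqn{V_n/2} of the specified torsion types to the
#' solvation-aware residual profile of [fit_target()]. With phases fixed at
#' 0/180 degrees the dihedral energy is linear in the amplitudes, so the fit
#' is a weighted linear least squares. Contributions are summed over all
#' instances of each fitted type within a conformer. The design matrix rank
#' is checked before solving; a rank-deficient design raises an error naming
#' the collinear columns.
#'
#' @param records list of [conformer_record()] objects.
#' @param spec a [fit_spec()].
#' @return list of class `"fourier_fit"` with elements `types` (fitted
#'   [torsion_type()] objects), `offset`, `coefficients`, `std_errors`,
#'   `residuals`, `fitted`, `rmse` and `condition_number`.
#' @export
fit_fourier <- function(records, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  y <- fit_target(records, shift = FALSE)
  n <- length(y)
  cols <- list()
  labels <- character(0)
  for (t_idx in seq_along(spec$types)) {
    tt <- spec$types[[t_idx]]
    ids <- spec$instances[[t_idx]]
    phis <- t(vapply(records, function(rec) {
      v <- rec$dihedral_values[ids]
      if (anyNA(v)) stop(sprintf(
        "conformer record is missing dihedral instance(s): %s",
        paste(ids[is.na(v)], collapse = ", ")))
      v
    }, numeric(length(ids))))
    if (length(ids) == 1L) phis <- matrix(phis, ncol = 1L)
    for (k in seq_along(tt$terms)) {
      tm <- tt$terms[[k]]
      basis <- rowSums(
        (1 + cos(deg2rad(tm$periodicity * phis - tm$phase))) / tm$divider)
      cols <- c(cols, list(basis))
      labels <- c(labels,
                  sprintf("%s:n%d_g%g", names(spec$instances)[t_idx],
                          tm$periodicity, tm$phase))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  if (spec$include_offset) {
    X <- cbind(X, offset = 1)
  }
  n_par <- ncol(X)
  if (n < n_par) {
    stop(sprintf("need at least %d conformers for %d free parameters",
                 n_par, n_par))
  }
  w <- spec$weights
  if (is.null(w) && !is.null(spec$boltzmann_T)) {
    RT <- 1.987204e-3 * spec$boltzmann_T
    w <- exp(-fit_target(records, shift = TRUE) / RT)
  }
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  qx <- qr(Xw)
  if (qx$rank < n_par) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):n_par]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qx, yw)
  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  dof <- max(n - n_par, 1L)
  sigma2 <- sum(w * resid^2) / dof
  XtX_inv <- matrix(0, n_par, n_par)
  XtX_inv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(XtX_inv) * sigma2, 0))
  names(se) <- colnames(X)
  sv <- svd(Xw, nu = 0, nv = 0)$d
  kappa <- sv[1] / sv[length(sv)]
  # write amplitudes back into the type skeletons
  fitted_types <- spec$types
  pos <- 0L
  for (t_idx in seq_along(fitted_types)) {
    for (k in seq_along(fitted_types[[t_idx]]$terms)) {
      pos <- pos + 1L
      fitted_types[[t_idx]]$terms[[k]]$half_barrier <- unname(beta[pos])
    }
  }
  structure(list(
    types = fitted_types,
    offset = if (spec$include_offset) unname(beta[n_par]) else 0,
    coefficients = beta,
    std_errors = se,
    residuals = resid,
    fitted = fitted,
    rmse = sqrt(mean(resid^2)),
    condition_number = kappa), class = "fourier_fit")
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("Fourier torsion fit: %d type(s), RMSE %.4f kcal/mol, cond %.3g\n",
              length(x$types), x$rmse, x$condition_number))
  print(x$coefficients)
  invisible(x)
}

#' Empirical minimum adjustment of a torsion potential
#'
#' Post-hoc adjustment used after a QM-based refit: shift the energy of the
#' fitted torsion at the centre of a target pseudorotation window (typically
#' the north minimum near \eqn{P = 18^\circ}) by `delta_e` while pinning the
#' current south-minimum energy. The amplitude corrections are the
#' minimum-norm solution of the two linear constraints over the existing
#' terms; if the constraints cannot be met with the available periodicities
#' (residual above `tol`), an infeasibility error is raised. After applying
#' the correction the achieved energy changes are re-evaluated on a phase
#' grid; the relocated S-minimum must move by less than 10% of `delta_e`.
#'
#' @param tt a [torsion_type()] whose amplitudes are adjusted.
#' @param center centre of the target pseudorotation window (degrees).
#' @param delta_e requested energy change at the window centre (kcal/mol).
#' @param tau_m puckering amplitude used to map phases to dihedral values.
#' @param angle_fun function mapping a phase P to the torsion's dihedral
#'   value (degrees); defaults to the \eqn{\nu_1} ring scan mapping of
#'   [scan_constraints()].
#' @param tol feasibility tolerance on the constraint residual (kcal/mol).
#' @return adjusted `torsion_type` with attribute `report`: a list with the
#'   achieved energy change at the window centre and at the relocated
#'   S-minimum.
#' @export
empirical_adjustment <- function(tt, center = 18, delta_e, tau_m = 35,
                                 angle_fun = NULL, tol = 1e-8) {
  stopifnot(inherits(tt, "torsion_type"), is.finite(delta_e))
  if (is.null(angle_fun)) {
    angle_fun <- function(P) scan_constraints(P, tau_m)$tau1
  }
  if (delta_e == 0) {
    attr(tt, "report") <- list(achieved_center = 0, achieved_s_min = 0,
                               feasible = TRUE)
    return(tt)
  }
  grid <- seq(0, 359, by = 1)
  phi_grid <- angle_fun(grid)
  e_old <- dihedral_energy(tt, phi_grid)
  s_region <- classify_pucker(grid) == "S"
  p_s <- grid[s_region][which.min(e_old[s_region])]
  phi_c <- angle_fun(center)
  phi_s <- angle_fun(p_s)
  basis <- function(phi) vapply(tt$terms, function(tm)
    (1 + cos(deg2rad(tm$periodicity * phi - tm$phase))) / tm$divider,
    numeric(1))
  A <- rbind(basis(phi_c), basis(phi_s))
  target <- c(delta_e, 0)
  d <- as.vector(pinv(A) %*% target)
  if (vnorm(A %*% d - target) > max(tol, 1e-10 * abs(delta_e))) {
    stop(sprintf(
      "infeasible adjustment: periodicities {%s} cannot change P=%g by %g while pinning the S minimum (residual %.3g)",
      paste(vapply(tt$terms, `[[`, integer(1), "periodicity"), collapse = ","),
      center, delta_e, vnorm(A %*% d - target)))
  }
  new_tt <- tt
  for (k in seq_along(new_tt$terms)) {
    new_tt$terms[[k]]$half_barrier <- new_tt$terms[[k]]$half_barrier + d[k]
  }
  e_new <- dihedral_energy(new_tt, phi_grid)
  p_s_new <- grid[s_region][which.min(e_new[s_region])]
  achieved_center <- dihedral_energy(new_tt, phi_c) - dihedral_energy(tt, phi_c)
  achieved_s <- min(e_new[s_region]) - min(e_old[s_region])
  if (abs(achieved_s) >= 0.1 * abs(delta_e)) {
    stop(sprintf(
      "infeasible adjustment: S minimum moved by %.4f kcal/mol (>= 10%% of |delta_e|)",
      achieved_s))
  }
  attr(new_tt, "report") <- list(
    achieved_center = achieved_center,
    achieved_s_min = achieved_s,
    s_min_phase_before = p_s, s_min_phase_after = p_s_new,
    amplitude_corrections = d, feasible = TRUE)
  new_tt
}
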