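#' Flat-well restraint
#'
#' A flat-bottomed penalty: zero on `[lower_flat, upper_flat]`, with one-sided
#' parabolic walls `k_lower * (lower_flat - x)^2` below and
#' `k_upper * (x - upper_flat)^2` above. The defaults are the terminal
#' base-pair hydrogen-bond well used to suppress fraying in duplex
#' simulations: flat between 2.5 and 3.2 angstrom, with 20 kcal/(mol A^2)
#' below and 30 kcal/(mol A^2) above.
#'
#' @param lower_flat,upper_flat flat-region edges (native units, angstrom or
#'   degrees); `lower_flat <= upper_flat`.
#' @param k_lower,k_upper force constants, kcal/(mol unit^2), `>= 0`.
#' @return list of class `"flat_well"`.
#' @export
flat_well <- function(lower_flat = 2.5, upper_flat = 3.2,
                      k_lower = 20, k_upper = 30) {
  stopifnot(is.finite(lower_flat), is.finite(upper_flat),
            lower_flat <= upper_flat, k_lower >= 0, k_upper >= 0)
  structure(list(lower_flat = lower_flat, upper_flat = upper_flat,
                 k_lower = k_lower, k_upper = k_upper),
            class = "flat_well")
}

#' Flat-well restraint energy
#'
#' Evaluates a [flat_well()] penalty: continuous and once-differentiable at
#' both walls, zero exactly on the flat interval, nonnegative everywhere.
#'
#' @param x coordinate value(s) in the well's native units.
#' @param w a [flat_well()].
#' @return energies in kcal/mol, same length as `x`.
#' @export
#' @examples
#' w <- flat_well()          # terminal-pair hydrogen-bond well
#' flat_well_energy(3.0, w)  # 0
#' flat_well_energy(3.7, w)  # 30 * 0.5^2 = 7.5
flat_well_energy <- function(x, w = flat_well()) {
  stopifnot(inherits(w, "flat_well"), all(is.finite(x)))
  below <- pmax(w$lower_flat - x, 0)
  above <- pmax(x - w$upper_flat, 0)
  w$k_lower * below^2 + w$k_upper * above^2
}

#' Glycosidic-angle flat-well restraint energy
#'
#' Angular flat well used to keep the glycosidic torsion chi of free
#' nucleosides in the anti region: zero on `[lower, upper]` degrees (defaults
#' 160 and 310), with a quadratic penalty `k * (delta in radians)^2`
#' (default 10 kcal/rad^2) outside. The angle is wrapped and the penalty
#' distance is measured to the nearest wall through the shorter angular
#' path, so the well is periodic and the penalty is continuous at the point
#' of the excluded arc farthest from both walls.
#'
#' @param chi glycosidic angle(s) in degrees (any wrap).
#' @param lower,upper closed well edges in degrees.
#' @param k force constant in kcal/(mol rad^2).
#' @return energies in kcal/mol.
#' @export
#' @examples
#' chi_well_energy(200)  # 0 (inside)
#' chi_well_energy(150)  # 10 * (10 * pi/180)^2 ~ 0.3046
chi_well_energy <- function(chi, lower = 160, upper = 310, k = 10) {
  stopifnot(all(is.finite(chi)), lower < upper)
  w <- wrap360(chi)
  inside <- w >= lower & w <= upper
  d_low <- abs(angle_diff(w, lower))
  d_up <- abs(angle_diff(w, upper))
  delta <- deg2rad(pmin(d_low, d_up))
  ifelse(inside, 0, k * delta^2)
}
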