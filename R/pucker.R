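#' Pseudorotation algebra for furanose rings
#'
#' The five endocyclic deoxyribose torsions \eqn{\nu_0 \ldots \nu_4} are
#' described by two parameters: the pseudorotation phase \eqn{P} and the
#' puckering amplitude \eqn{\tau_m}, via the Altona--Sundaralingam relation
#' \deqn{\nu_j = \tau_m \cos(P + (j - 2)\,144^\circ),}
#' so that \eqn{\nu_2 = \tau_m \cos P}. North (N, C3'-endo) sugars around
#' \eqn{P \approx 18^\circ} characterize A-form nucleotides, south
#' (S, C2'-endo) sugars around \eqn{P \approx 150^\circ} the B-form.
#'
#' `pseudorotation()` inverts the relation: the phase is obtained from
#' \deqn{\tan P = \frac{(\nu_4 + \nu_1) - (\nu_3 + \nu_0)}
#'                    {2 \nu_2 (\sin 36^\circ + \sin 72^\circ)}}
#' evaluated with `atan2` so the \eqn{\cos P = 0} pole is never hit, and the
#' amplitude as the pole-free modulus
#' \eqn{\tau_m = \sqrt{\nu_2^2 + s^2}} with
#' \eqn{s = [(\nu_4+\nu_1)-(\nu_3+\nu_0)]/[2(\sin 36^\circ + \sin 72^\circ)]},
#' which coincides with \eqn{\nu_2 / \cos P} on any torsion set generated by
#' the forward map.
#'
#' @param nu numeric vector of the five ring torsions
#'   \eqn{\nu_0 = } C4'-O4'-C1'-C2', \eqn{\nu_1 = } O4'-C1'-C2'-C3',
#'   \eqn{\nu_2 = } C1'-C2'-C3'-C4', \eqn{\nu_3 = } C2'-C3'-C4'-O4',
#'   \eqn{\nu_4 = } C3'-C4'-O4'-C1', in degrees.
#' @return A list of class `"pucker_state"` with elements `P` (degrees in
#'   \eqn{[0, 360)}), `tau_m` (degrees, \eqn{\ge 0}) and `pucker_class`
#'   (`"N"` or `"S"`).
#' @seealso [ring_torsions_from_phase()], [classify_pucker()]
#' @export
#' @examples
#' nu <- ring_torsions_from_phase(18, 38)
#' pseudorotation(nu)  # recovers P = 18, tau_m = 38
pseudorotation <- function(nu) {
  if (length(nu) != 5L || !all(is.finite(nu))) {
    stop("'nu' must be five finite ring torsions (nu0..nu4)")
  }
  if (all(abs(nu) < 1e-9)) {
    stop("planar ring: all ring torsions are zero, P is undefined")
  }
  s3672 <- sin(deg2rad(36)) + sin(deg2rad(72))
  a <- (nu[5] + nu[2]) - (nu[4] + nu[1])  # (nu4 + nu1) - (nu3 + nu0)
  s <- a / (2 * s3672)                     # tau_m * sin(P)
  P <- wrap360(rad2deg(atan2(s, nu[3])))
  tau_m <- sqrt(nu[3]^2 + s^2)
  structure(list(P = P, tau_m = tau_m, pucker_class = classify_pucker(P)),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("pucker: P = %.3f deg, tau_m = %.3f deg, class = %s\n",
              x$P, x$tau_m, x$pucker_class))
  invisible(x)
}

#' Inverse pseudorotation map
#'
#' Generates the five endocyclic ring torsions corresponding to a phase and
#' amplitude, \eqn{\nu_j = \tau_m \cos(P + (j-2)\,144^\circ)}, wrapped to
#' \eqn{[-180, 180)}. [pseudorotation()] applied to the result round-trips
#' `(P, tau_m)` to numerical precision.
#'
#' @param P pseudorotation phase in degrees.
#' @param tau_m puckering amplitude in degrees, \eqn{\ge 0}.
#' @return numeric vector `c(nu0, ..., nu4)` in degrees.
#' @export
ring_torsions_from_phase <- function(P, tau_m) {
  stopifnot(is.finite(P), is.finite(tau_m))
  if (tau_m < 0) stop("'tau_m' must be >= 0")
  j <- 0:4
  wrap180(tau_m * cos(deg2rad(P + (j - 2) * 144)))
}

#' Classify a pseudorotation phase as north or south
#'
#' A sugar is north (N) if its wrapped phase lies in the open interval
#' \eqn{(-90^\circ, 90^\circ)} and south (S) otherwise; the boundary values
#' \eqn{\pm 90^\circ} are S by the strict inequality.
#'
#' @param P pseudorotation phase(s) in degrees (any wrap).
#' @return character vector of `"N"`/`"S"`.
#' @export
#' @examples
#' classify_pucker(c(18, 150, 90, 342))  # N S S N
classify_pucker <- function(P) {
  stopifnot(all(is.finite(P)))
  w <- wrap180(P)
  ifelse(w > -90 & w < 90, "N", "S")
}

#' Pseudorotation phases for a constrained pucker scan
#'
#' Evenly spaced target phases for a constrained conformer scan, by default
#' the full pseudorotation cycle 0--360 degrees at 10 degree intervals
#' (36 points; the stop value is an exclusive endpoint equal to start + 360).
#'
#' @param start,stop,step scan range and spacing in degrees; `step` must
#'   divide `stop - start` exactly.
#' @return numeric vector of phases, `stop` excluded.
#' @export
scan_targets <- function(start = 0, stop = 360, step = 10) {
  if (!is.finite(step) || step <= 0) stop("'step' must be positive")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9) {
    stop(sprintf("'step' (%g) does not divide the range %g-%g", step, start, stop))
  }
  start + step * seq_len(round(n)) - step
}

#' Constrained dihedral values for a pucker-scan point
#'
#' For a conformer scan along the pseudorotation cycle, two dihedrals are
#' constrained at each phase: the ring scan torsion tau1 (by default the
#' endocyclic \eqn{\nu_1} = O4'-C1'-C2'-C3') taken directly from the inverse
#' pseudorotation map, and the backbone torsion \eqn{\delta}
#' (C5'-C4'-C3'-O3'), which is not itself a ring torsion but tracks its ring
#' counterpart \eqn{\nu_3} up to an approximately constant exocyclic offset:
#' \eqn{\delta = \nu_3 + \Delta\delta}. The default offset was calibrated
#' once against the packaged fiber-model duplex geometry.
#'
#' @param P pseudorotation phase in degrees (vectorized).
#' @param tau_m puckering amplitude in degrees, > 0.
#' @param tau1_index which endocyclic torsion (0-4) serves as the ring scan
#'   dihedral; default 1 (\eqn{\nu_1}).
#' @param tau1_offset additive offset applied to the ring scan dihedral, in
#'   degrees (default 0: the scan dihedral is the ring torsion itself).
#' @param delta_offset exocyclic offset \eqn{\Delta\delta} in degrees.
#' @return data frame with columns `P`, `tau1`, `delta` (degrees; `tau1`
#'   wrapped to \eqn{[-180, 180)}, `delta` to \eqn{[0, 360)}).
#' @export
scan_constraints <- function(P, tau_m, tau1_index = 1, tau1_offset = 0,
                             delta_offset = 123.2) {
  stopifnot(is.finite(tau_m), tau_m > 0, tau1_index %in% 0:4)
  tau1 <- vapply(P, function(p) {
    nu <- ring_torsions_from_phase(p, tau_m)
    wrap180(nu[tau1_index + 1L] + tau1_offset)
  }, numeric(1))
  delta <- vapply(P, function(p) {
    nu <- ring_torsions_from_phase(p, tau_m)
    wrap360(nu[4] + delta_offset)
  }, numeric(1))
  data.frame(P = P, tau1 = tau1, delta = delta)
}
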