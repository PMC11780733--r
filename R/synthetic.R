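#' Two-state pucker time-series specification
#'
#' Parameters of the synthetic trajectory generator: each residue's sugar
#' hops between a north state (mean phase `mean_P_N`) and a south state
#' (mean phase `mean_P_S`) following a hidden two-state Markov chain with
#' stationary north probability `p_N` and mean north dwell time
#' `switch_time` frames (the south dwell follows from detailed balance as
#' `switch_time * (1 - p_N) / p_N`). The emitted phase is the state mean
#' plus wrapped Gaussian noise of width `sigma_P`. Backbone angles are
#' emitted from categorical substate mixtures with the same rotamer-window
#' conventions used by the classifiers, so classification recovery is exact
#' by construction.
#'
#' The defaults emulate a B-DNA duplex in water: a predominantly south
#' ensemble (\eqn{p_N = 0.15}) with the north mean at the \eqn{P = 18}
#' degree minimum and the south mean at 150 degrees, and north/south
#' interconversion fast relative to the trajectory length.
#'
#' @param p_N stationary probability of the north state, in \[0, 1\].
#' @param mean_P_N,mean_P_S state mean phases (degrees).
#' @param sigma_P emission noise width (degrees), > 0.
#' @param switch_time mean north-state dwell, in frames (>= 1);
#'   `1 / (1 - p_N)` makes successive frames independent (memoryless
#'   chain).
#' @param n_frames,n_residues series dimensions.
#' @param frame_ps frame spacing in picoseconds (metadata only).
#' @param p_BII per-frame probability of the BII backbone substate (the
#'   rest is BI); `p_ag_flip` the probability of the noncanonical
#'   alpha/gamma = g+/t substate (the rest canonical g-/g+).
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed.
#' @return list of class `"two_state_spec"`.
#' @export
two_state_spec <- function(p_N = 0.15, mean_P_N = 18, mean_P_S = 150,
                           sigma_P = 12, switch_time = 50,
                           n_frames = 1000, n_residues = 1, frame_ps = 10,
                           p_BII = 0.25, p_ag_flip = 0.015, seed = 1) {
  stopifnot(p_N >= 0, p_N <= 1, sigma_P > 0, switch_time >= 1,
            n_frames >= 1, n_residues >= 1,
            p_BII >= 0, p_BII <= 1, p_ag_flip >= 0, p_ag_flip <= 1)
  structure(list(p_N = p_N, mean_P_N = mean_P_N, mean_P_S = mean_P_S,
                 sigma_P = sigma_P, switch_time = switch_time,
                 n_frames = n_frames, n_residues = n_residues,
                 frame_ps = frame_ps, p_BII = p_BII,
                 p_ag_flip = p_ag_flip, seed = as.integer(seed)),
            class = "two_state_spec")
}

## Alternating-dwell simulation of the two-state chain: dwell lengths are
## geometric with the state's mean; the initial state is drawn from the
## stationary law. Returns a logical vector (TRUE = north).
.simulate_states <- function(n, p_N, switch_time) {
  if (p_N == 0) return(rep(FALSE, n))
  if (p_N == 1) return(rep(TRUE, n))
  leave_N <- min(1 / switch_time, 1)
  dwell_S <- switch_time * (1 - p_N) / p_N
  leave_S <- min(1 / dwell_S, 1)
  state <- stats::runif(1) < p_N
  out <- logical(n)
  pos <- 0L
  while (pos < n) {
    p_leave <- if (state) leave_N else leave_S
    d <- 1L + stats::rgeom(1, p_leave)
    idx <- (pos + 1L):min(pos + d, n)
    out[idx] <- state
    pos <- pos + d
    state <- !state
  }
  out
}

## Draw angles uniformly inside a rotamer window, inset from the edges so
## classification of the emitted angle is unambiguous.
.draw_in_window <- function(n, window) {
  lims <- switch(window,
                 "g+" = c(0, 120), "t" = c(120, 240), "g-" = c(240, 360))
  stats::runif(n, lims[1] + 10, lims[2] - 10)
}

#' Simulate a two-state pucker/backbone dihedral series
#'
#' Generates a per-frame, per-residue angle series from a
#' [two_state_spec()]: hidden north/south Markov chains for the
#' pseudorotation phase, and independent categorical draws for the
#' epsilon/zeta (BI vs BII) and alpha/gamma (canonical vs g+/t) backbone
#' substates. The planted ground truth (including the realized hidden
#' states) is attached as attribute `"truth"`, so downstream estimators are
#' always tested against the generator, never against themselves.
#'
#' @param spec a [two_state_spec()].
#' @return data frame with columns `frame`, `chain`, `resid`, `P`,
#'   `epsilon`, `zeta`, `alpha`, `gamma`; attribute `"truth"` carries the
#'   spec and per-residue hidden state matrix.
#' @export
simulate_pucker_series <- function(spec = two_state_spec()) {
  stopifnot(inherits(spec, "two_state_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  nr <- spec$n_residues
  states <- matrix(FALSE, nf, nr)
  out <- vector("list", nr)
  for (r in seq_len(nr)) {
    s <- .simulate_states(nf, spec$p_N, spec$switch_time)
    states[, r] <- s
    mu <- ifelse(s, spec$mean_P_N, spec$mean_P_S)
    P <- wrap360(mu + stats::rnorm(nf, 0, spec$sigma_P))
    bii <- stats::runif(nf) < spec$p_BII
    epsilon <- ifelse(bii, .draw_in_window(nf, "g-"), .draw_in_window(nf, "t"))
    zeta <- ifelse(bii, .draw_in_window(nf, "t"), .draw_in_window(nf, "g-"))
    agf <- stats::runif(nf) < spec$p_ag_flip
    alpha <- ifelse(agf, .draw_in_window(nf, "g+"), .draw_in_window(nf, "g-"))
    gamma <- ifelse(agf, .draw_in_window(nf, "t"), .draw_in_window(nf, "g+"))
    out[[r]] <- data.frame(frame = seq_len(nf), chain = "A", resid = r,
                           P = P, epsilon = epsilon, zeta = zeta,
                           alpha = alpha, gamma = gamma)
  }
  series <- do.call(rbind, out)
  attr(series, "truth") <- list(spec = spec, states = states)
  series
}

#' Synthetic torsion scan with planted Fourier coefficients
#'
#' Builds a conformer-scan record set whose solvation-aware fit target
#' ([fit_target()]) reproduces, exactly at zero noise, the energy profile of
#' the planted torsion types evaluated along the constrained pucker scan:
#' dihedral-instance values come from the [scan_constraints()] mapping and
#' the QM gas-phase energy carries the planted torsion energy (plus offset
#' and optional i.i.d. Gaussian noise), while the remaining components are
#' zero. [fit_fourier()] on the result recovers the planted amplitudes to
#' numerical precision when `noise_sd = 0`.
#'
#' @param planted named list of [torsion_type()] objects with the planted
#'   amplitudes; names are the dihedral instance ids. The first type is
#'   mapped to the ring scan dihedral `tau1`, the second (if present) to
#'   `delta`; further types cycle over the two mappings.
#' @param offset constant energy offset added to every conformer (kcal/mol).
#' @param noise_sd standard deviation of i.i.d. Gaussian noise added to the
#'   QM energies (kcal/mol); 0 for a noiseless scan.
#' @param tau_m scan amplitude (degrees).
#' @param P phases of the scan (default the standard 36-point grid).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return list of [conformer_record()]s with attribute `"truth"` (planted
#'   types, offset, noise draws).
#' @export
synth_scan <- function(planted, offset = 0, noise_sd = 0, tau_m = 35,
                       P = scan_targets(), seed = 1) {
  stopifnot(length(planted) >= 1L,
            all(vapply(planted, inherits, logical(1), "torsion_type")))
  if (is.null(names(planted))) {
    names(planted) <- paste0("tors", seq_along(planted))
  }
  sc <- scan_constraints(P, tau_m)
  maps <- list(sc$tau1, wrap180(sc$delta))
  noise <- if (noise_sd > 0) {
    set.seed(seed)
    stats::rnorm(length(P), 0, noise_sd)
  } else rep(0, length(P))
  records <- lapply(seq_along(P), function(i) {
    phi <- vapply(seq_along(planted), function(k) maps[[(k - 1L) %% 2L + 1L]][i],
                  numeric(1))
    names(phi) <- names(planted)
    e <- sum(vapply(seq_along(planted), function(k)
      dihedral_energy(planted[[k]], phi[k]), numeric(1)))
    conformer_record(P[i], phi, e_qm_gas = e + offset + noise[i])
  })
  attr(records, "truth") <- list(planted = planted, offset = offset,
                                 noise = noise, tau_m = tau_m, P = P)
  records
}
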