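## Gas constant in kcal/(mol K); RT at 298.15 K = 0.59248 kcal/mol.
.R_KCAL <- 1.987204e-3

#' Angular rotamer windows
#'
#' Tripartite rotamer convention used for backbone substate classification:
#' g+ = \[0, 120), t = \[120, 240), g- = \[240, 360) degrees.
#'
#' @param x angles in degrees (any wrap).
#' @return character vector of `"g+"`, `"t"`, `"g-"`.
#' @export
rotamer_window <- function(x) {
  w <- wrap360(x)
  out <- character(length(w))
  out[w < 120] <- "g+"
  out[w >= 120 & w < 240] <- "t"
  out[w >= 240] <- "g-"
  out
}

#' Classify the epsilon/zeta backbone substate
#'
#' BI is the canonical B-DNA backbone substate with \eqn{\epsilon/\zeta} =
#' t/g-; BII has the roles swapped (g-/t); any other rotamer combination is
#' reported as `"other"`. Windows follow [rotamer_window()].
#'
#' @param epsilon,zeta backbone dihedrals in degrees (vectorized).
#' @return character vector of `"BI"`, `"BII"`, `"other"` (`NA` propagates).
#' @export
#' @examples
#' classify_bi_bii(181, 267)  # BI
#' classify_bi_bii(270, 180)  # BII
classify_bi_bii <- function(epsilon, zeta) {
  out <- rep(NA_character_, length(epsilon))
  ok <- is.finite(epsilon) & is.finite(zeta)
  we <- rotamer_window(epsilon[ok])
  wz <- rotamer_window(zeta[ok])
  res <- rep("other", sum(ok))
  res[we == "t" & wz == "g-"] <- "BI"
  res[we == "g-" & wz == "t"] <- "BII"
  out[ok] <- res
  out
}

#' Classify the alpha/gamma backbone substate
#'
#' The canonical B-DNA combination is \eqn{\alpha/\gamma} = g-/g+; the
#' noncanonical flip historically overpopulated by unrefined force fields is
#' g+/t. Everything else is `"other"`.
#'
#' @param alpha,gamma backbone dihedrals in degrees (vectorized).
#' @return character vector of `"canonical"`, `"g+/t"`, `"other"`.
#' @export
#' @examples
#' classify_alpha_gamma(295, 52)  # canonical
classify_alpha_gamma <- function(alpha, gamma) {
  out <- rep(NA_character_, length(alpha))
  ok <- is.finite(alpha) & is.finite(gamma)
  wa <- rotamer_window(alpha[ok])
  wg <- rotamer_window(gamma[ok])
  res <- rep("other", sum(ok))
  res[wa == "g-" & wg == "g+"] <- "canonical"
  res[wa == "g+" & wg == "t"] <- "g+/t"
  out[ok] <- res
  out
}

## Residues retained after dropping `k` residues from each end of each chain.
## `series` needs chain + resid columns; residue order within a chain follows
## sorted resid.
.retained_residues <- function(series, exclude_terminal) {
  info <- unique(series[, c("chain", "resid")])
  keep <- logical(nrow(info))
  for (ch in unique(info$chain)) {
    idx <- which(info$chain == ch)
    ord <- idx[order(info$resid[idx])]
    n <- length(ord)
    if (n > 2 * exclude_terminal) {
      keep[ord[(exclude_terminal + 1L):(n - exclude_terminal)]] <- TRUE
    }
  }
  info[keep, , drop = FALSE]
}

#' Percentage of north sugar pucker
#'
#' Fraction of frames (as a percentage) in which each residue's
#' pseudorotation phase classifies as north, plus an aggregate over all
#' residues after excluding a given number of terminal residues from each
#' end of each chain (terminal base pairs fray and are conventionally
#' excluded from pucker statistics).
#'
#' @param series data frame with columns `frame`, `chain`, `resid` and `P`
#'   (pseudorotation phase in degrees), e.g. from
#'   [simulate_pucker_series()] or [angles_from_structure()].
#' @param exclude_terminal number of residues dropped from each end of each
#'   chain for the aggregate (default 0).
#' @return list with `per_residue` (data frame: chain, resid, n_frames,
#'   percent_N) and `aggregate` (percentage over all retained residue
#'   frames).
#' @export
percent_N <- function(series, exclude_terminal = 0) {
  stopifnot(all(c("chain", "resid", "P") %in% names(series)), nrow(series) > 0)
  is_n <- classify_pucker(series$P) == "N"
  agg <- stats::aggregate(is_n, by = list(chain = series$chain, resid = series$resid),
                   FUN = function(v) c(mean(v) * 100, length(v)))
  per_res <- data.frame(chain = agg$chain, resid = agg$resid,
                        n_frames = agg$x[, 2], percent_N = agg$x[, 1])
  per_res <- per_res[order(per_res$chain, per_res$resid), , drop = FALSE]
  rownames(per_res) <- NULL
  kept <- .retained_residues(series, exclude_terminal)
  if (nrow(kept) == 0L) {
    stop("terminal exclusion leaves no residues to aggregate")
  }
  key <- paste(series$chain, series$resid)
  in_kept <- key %in% paste(kept$chain, kept$resid)
  list(per_residue = per_res,
       aggregate = mean(is_n[in_kept]) * 100,
       n_residues_aggregated = nrow(kept))
}

#' Potential of mean force of the pseudorotation angle
#'
#' Histogram-based PMF of a periodic angle:
#' \deqn{\mathrm{PMF}(b) = -RT \ln(n_b / n_{max}),}
#' where \eqn{n_b} is the count in bin \eqn{b} and \eqn{n_{max}} the count of
#' the most populated bin, so the PMF minimum is exactly zero at the modal
#' bin. Empty bins are reported as `NA`, never clamped to a finite ceiling.
#'
#' 95% confidence intervals on the counts are computed as
#' \eqn{\pm 1.96 \times} SEM, with the SEM obtained by block averaging over
#' `n_blocks` equal time blocks (frames from simulations are autocorrelated;
#' block averaging gives an honest SEM when blocks exceed the correlation
#' time). Count intervals are propagated through the log to PMF bounds
#' `ci_low`/`ci_high`; when the lower count bound is non-positive the upper
#' PMF bound is `NA`.
#'
#' @param p numeric vector of angles in degrees, in time order.
#' @param bin bin width in degrees (must divide 360; default 3).
#' @param temperature temperature in kelvin (default 298.15).
#' @param n_blocks number of time blocks for the SEM (default 10).
#' @return data frame of class `"pmf_profile"` with columns `center`,
#'   `count`, `pmf`, `ci_low`, `ci_high`; attributes `temperature`, `RT`,
#'   `n_frames`.
#' @export
#' @examples
#' x <- c(rep(10, 272), rep(100, 100))  # count ratio ~ e
#' prof <- pmf(x, bin = 10)
pmf <- function(p, bin = 3, temperature = 298.15, n_blocks = 10) {
  stopifnot(length(p) > 0, bin > 0, abs(360 / bin - round(360 / bin)) < 1e-9)
  w <- wrap360(p)
  nb <- round(360 / bin)
  idx <- pmin(floor(w / bin), nb - 1L) + 1L
  counts <- tabulate(idx, nbins = nb)
  if (!any(counts > 0)) stop("no nonempty bins")
  nmax <- max(counts)
  RT <- .R_KCAL * temperature
  val <- ifelse(counts > 0, -RT * log(counts / nmax), NA_real_)
  # block-averaged SEM of per-bin counts (scaled block proportions)
  n <- length(p)
  blocks <- pmin(floor((seq_len(n) - 1L) / (n / n_blocks)), n_blocks - 1L) + 1L
  ci <- rep(NA_real_, nb)
  if (n_blocks >= 2 && n >= n_blocks) {
    prop_b <- vapply(seq_len(n_blocks), function(b) {
      sel <- blocks == b
      tabulate(idx[sel], nbins = nb) / sum(sel)
    }, numeric(nb))
    sem_prop <- apply(prop_b, 1, stats::sd) / sqrt(n_blocks)
    ci <- 1.96 * sem_prop * n
  }
  lo_count <- counts - ci
  hi_count <- counts + ci
  ci_low <- ifelse(counts > 0 & is.finite(hi_count) & hi_count > 0,
                   -RT * log(pmax(hi_count, 1e-300) / nmax), NA_real_)
  ci_high <- ifelse(counts > 0 & is.finite(lo_count) & lo_count > 0,
                    -RT * log(pmax(lo_count, 1e-300) / nmax), NA_real_)
  out <- data.frame(center = (seq_len(nb) - 0.5) * bin, count = counts,
                    pmf = val, ci_low = ci_low, ci_high = ci_high)
  attr(out, "temperature") <- temperature
  attr(out, "RT") <- RT
  attr(out, "n_frames") <- n
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Backbone substate populations
#'
#' Per-residue percentages of the epsilon/zeta (BI, BII, other) and
#' alpha/gamma (canonical, g+/t, other) backbone substates, plus aggregates
#' with terminal-residue exclusion. Percentages sum to 100 per residue and
#' classification family.
#'
#' @param series data frame with columns `frame`, `chain`, `resid` and the
#'   backbone dihedrals `epsilon`, `zeta`, `alpha`, `gamma` (degrees).
#'   Frames with `NA` angles (e.g. chain-terminal residues whose epsilon or
#'   zeta is undefined) are dropped from the corresponding family.
#' @param exclude_terminal residues dropped from each end of each chain in
#'   the aggregate (default 0).
#' @return list with `per_residue` (data frame of percentages) and
#'   `aggregate` (named percentages over retained residues).
#' @export
substate_populations <- function(series, exclude_terminal = 0) {
  stopifnot(all(c("chain", "resid") %in% names(series)))
  ez <- if (all(c("epsilon", "zeta") %in% names(series))) {
    classify_bi_bii(series$epsilon, series$zeta)
  } else rep(NA_character_, nrow(series))
  ag <- if (all(c("alpha", "gamma") %in% names(series))) {
    classify_alpha_gamma(series$alpha, series$gamma)
  } else rep(NA_character_, nrow(series))
  pct <- function(lab, lev) {
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L) return(stats::setNames(rep(NA_real_, length(lev)), lev))
    100 * vapply(lev, function(l) mean(lab == l), numeric(1))
  }
  ez_lev <- c("BI", "BII", "other")
  ag_lev <- c("canonical", "g+/t", "other")
  info <- unique(series[, c("chain", "resid")])
  info <- info[order(info$chain, info$resid), , drop = FALSE]
  rows <- lapply(seq_len(nrow(info)), function(i) {
    sel <- series$chain == info$chain[i] & series$resid == info$resid[i]
    c(pct(ez[sel], ez_lev), pct(ag[sel], ag_lev))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("BI", "BII", "other_ez", "canonical", "gp_t", "other_ag")
  per_res <- cbind(info, as.data.frame(tab))
  rownames(per_res) <- NULL
  kept <- .retained_residues(series, exclude_terminal)
  if (nrow(kept) == 0L) stop("terminal exclusion leaves no residues")
  in_kept <- paste(series$chain, series$resid) %in%
    paste(kept$chain, kept$resid)
  list(per_residue = per_res,
       aggregate = c(pct(ez[in_kept], ez_lev)[c("BI", "BII")],
                     other_ez = unname(pct(ez[in_kept], ez_lev)["other"]),
                     pct(ag[in_kept], ag_lev)[c("canonical")],
                     gp_t = unname(pct(ag[in_kept], ag_lev)["g+/t"]),
                     other_ag = unname(pct(ag[in_kept], ag_lev)["other"])),
       n_residues_aggregated = nrow(kept))
}
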