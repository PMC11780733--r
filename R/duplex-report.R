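#' Full structural report for a DNA duplex
#'
#' Computes the standard descriptive battery for one duplex structure:
#' per-residue backbone/glycosidic angles and sugar pucker, intra-pair
#' parameters, base-pair step and local helical parameters, and groove
#' widths, then averages them with the conventional exclusions (a number of
#' terminal base pairs dropped from each end, and optionally backbone-angle
#' averages restricted to residues in the canonical BI backbone state).
#' Backbone angles, pucker phase and rotational parameters are averaged
#' circularly; translations and groove widths arithmetically.
#'
#' @param x a [build_fiber_duplex()] result, a `bio3d` pdb object, or a PDB
#'   file path.
#' @param pairing data frame with columns `chain1`, `resno1`, `chain2`,
#'   `resno2` mapping strand-1 residues to their Watson-Crick partners.
#'   Defaults to the builder's pairing for a `fiber_duplex`; for PDB input
#'   it must be supplied (no hydrogen-bond inference is attempted).
#' @param exclude_terminal base pairs dropped from each end in the averages
#'   (default 2).
#' @param bi_only restrict backbone-angle averages to BI-classified
#'   residues (default `FALSE`; residues with undefined epsilon/zeta are
#'   always excluded from the epsilon/zeta averages).
#' @param model MODEL selection for multi-model PDB input.
#' @return list of class `"duplex_report"` with `backbone`, `pairs`,
#'   `steps`, `helical`, `grooves` tables and a `summary` data frame (one
#'   row per parameter, averaged under the stated exclusions).
#' @export
duplex_report <- function(x, pairing = NULL, exclude_terminal = 2,
                          bi_only = FALSE, model = 1) {
  at <- .atom_table(x, model = model)
  at$elety <- .norm_elety(at$elety)
  if (is.null(pairing) && inherits(x, "fiber_duplex")) pairing <- x$pairing
  if (is.null(pairing)) {
    stop("a pairing map (chain1, resno1, chain2, resno2) is required for PDB input")
  }
  ang <- angles_from_structure(at)
  res_xyz <- function(ch, rn) {
    s <- at[at$chain == ch & at$resno == rn, , drop = FALSE]
    m <- as.matrix(s[, c("x", "y", "z")])
    rownames(m) <- s$elety
    m
  }
  res_name <- function(ch, rn) at$resid[at$chain == ch & at$resno == rn][1]
  np <- nrow(pairing)
  frames1 <- vector("list", np)
  frames2 <- vector("list", np)
  pair_ok <- logical(np)
  for (i in seq_len(np)) {
    ok <- tryCatch({
      frames1[[i]] <- base_frame(res_xyz(pairing$chain1[i], pairing$resno1[i]),
                                 res_name(pairing$chain1[i], pairing$resno1[i]))
      frames2[[i]] <- base_frame(res_xyz(pairing$chain2[i], pairing$resno2[i]),
                                 res_name(pairing$chain2[i], pairing$resno2[i]))
      TRUE
    }, error = function(e) {
      warning(sprintf("pair %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
    pair_ok[i] <- ok
  }
  pairs_tab <- NULL
  pair_frames <- vector("list", np)
  for (i in which(pair_ok)) {
    pp <- pair_parameters(frames1[[i]], frames2[[i]])
    pair_frames[[i]] <- attr(pp, "pair_frame")
    pairs_tab <- rbind(pairs_tab,
                       data.frame(pair = i, as.list(pp), check.names = FALSE))
  }
  steps_tab <- NULL
  heli_tab <- NULL
  for (i in seq_len(np - 1L)) {
    if (!pair_ok[i] || !pair_ok[i + 1L]) next
    st <- step_parameters(pair_frames[[i]], pair_frames[[i + 1L]])
    hp <- helical_parameters(pair_frames[[i]], pair_frames[[i + 1L]])
    steps_tab <- rbind(steps_tab,
                       data.frame(step = i, as.list(st), check.names = FALSE))
    heli_tab <- rbind(heli_tab,
                      data.frame(step = i, as.list(hp), check.names = FALSE))
  }
  # groove widths from phosphates of the two paired strands
  get_p <- function(ch, rns) {
    m <- t(vapply(rns, function(rn) {
      xyz <- res_xyz(ch, rn)
      if ("P" %in% rownames(xyz)) xyz["P", ] else rep(NA_real_, 3)
    }, numeric(3)))
    m[stats::complete.cases(m), , drop = FALSE]
  }
  grooves <- tryCatch({
    p1 <- get_p(pairing$chain1[1], pairing$resno1)
    p2 <- get_p(pairing$chain2[1], sort(pairing$resno2))
    groove_widths(p1, p2)
  }, error = function(e) NULL)

  # ---- averages with exclusions -------------------------------------------
  keep_pair <- rep(FALSE, np)
  if (np > 2 * exclude_terminal) {
    keep_pair[(exclude_terminal + 1L):(np - exclude_terminal)] <- TRUE
  }
  kept_res <- rbind(
    data.frame(chain = pairing$chain1[keep_pair],
               resno = pairing$resno1[keep_pair]),
    data.frame(chain = pairing$chain2[keep_pair],
               resno = pairing$resno2[keep_pair]))
  bb <- merge(ang, kept_res, by = c("chain", "resno"))
  if (bi_only && nrow(bb)) {
    st <- classify_bi_bii(bb$epsilon, bb$zeta)
    bb <- bb[!is.na(st) & st == "BI", , drop = FALSE]
  }
  avg <- c(
    alpha = circular_mean(bb$alpha), beta = circular_mean(bb$beta),
    gamma = circular_mean(bb$gamma), delta = circular_mean(bb$delta),
    epsilon = circular_mean(bb$epsilon), zeta = circular_mean(bb$zeta),
    chi = circular_mean(bb$chi), P = circular_mean(bb$P))
  sub_rows <- function(tab, idcol, keep_ids) {
    if (is.null(tab)) return(NULL)
    tab[tab[[idcol]] %in% keep_ids, , drop = FALSE]
  }
  pk <- which(keep_pair)
  pairs_k <- sub_rows(pairs_tab, "pair", pk)
  steps_k <- sub_rows(steps_tab, "step", pk[-length(pk)])
  heli_k <- sub_rows(heli_tab, "step", pk[-length(pk)])
  mean_cols <- function(tab, circ = character(0)) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    vapply(setdiff(names(tab), c("pair", "step")), function(cn) {
      if (cn %in% circ) circular_mean(tab[[cn]]) else
        mean(tab[[cn]], na.rm = TRUE)
    }, numeric(1))
  }
  avg <- c(avg,
           mean_cols(pairs_k, circ = c("buckle", "propeller", "opening")),
           mean_cols(steps_k, circ = c("tilt", "roll", "twist")),
           mean_cols(heli_k, circ = c("inclination", "tip", "htwist")))
  if (!is.null(grooves)) {
    gk <- grooves[grooves$level %in% pk, , drop = FALSE]
    if (nrow(gk)) {
      avg <- c(avg, minor_groove = mean(gk$minor, na.rm = TRUE),
               major_groove = mean(gk$major, na.rm = TRUE))
    }
  }
  structure(list(
    backbone = ang, pairs = pairs_tab, steps = steps_tab,
    helical = heli_tab, grooves = grooves,
    summary = data.frame(parameter = names(avg), value = unname(avg)),
    exclude_terminal = exclude_terminal, bi_only = bi_only),
    class = "duplex_report")
}

#' @export
print.duplex_report <- function(x, ...) {
  cat(sprintf("duplex report (%d terminal pair(s) excluded%s)\n",
              x$exclude_terminal, if (x$bi_only) ", BI-only backbone" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
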