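## ---------------------------------------------------------------------------
## Idealized fiber-model duplex builder. Base-pair frames are propagated
## along a straight global helical axis from planted helical parameters
## (htwist, hrise, inclination, tip, x-/y-displacement), ideal Watson-Crick
## bases are attached to each pair frame, and a deoxyribose/phosphate moiety
## with a prescribed sugar pucker (P, tau_m) and glycosidic angle chi is
## grown onto each base. Re-analysis of the built coordinates with the CEHS
## algebra recovers the planted helical parameters, which simultaneously
## validates the builder and the parameter algebra.
## ---------------------------------------------------------------------------

.fiber_forms <- list(
  B = list(htwist = 36.0, hrise = 3.38, inclination = 1.5, tip = 0,
           x_displacement = 0.0, y_displacement = 0.0,
           P = 150, tau_m = 36, chi = 250, gamma = 54, beta = 176),
  A = list(htwist = 32.7, hrise = 2.81, inclination = 20.7, tip = 0,
           x_displacement = -5.3, y_displacement = 0.0,
           P = 18, tau_m = 38, chi = 202, gamma = 54, beta = 175)
)

#' Fiber-model duplex specification
#'
#' Planted construction parameters for an idealized A- or B-form duplex.
#' The form defaults are the canonical reference geometries used to monitor
#' the A/B character of simulated DNA: the B-form has inclination 1.5
#' degrees and zero x-displacement, the A-form inclination 20.7 degrees and
#' x-displacement -5.3 angstrom, with form-appropriate sugar pucker (south,
#' P = 150 degrees, for B; north, P = 18 degrees, for A) and glycosidic
#' angle (high-anti ~250 degrees for B, anti ~202 degrees for A). Any
#' default can be overridden.
#'
#' @param form `"A"` or `"B"`.
#' @param sequence strand-1 base sequence, 5' to 3' (characters ACGT);
#'   strand 2 is its reverse complement.
#' @param ... named overrides of the form defaults (`htwist`, `hrise`,
#'   `inclination`, `tip`, `x_displacement`, `y_displacement`, `P`,
#'   `tau_m`, `chi`, `gamma`, `beta`).
#' @return list of class `"fiber_spec"`.
#' @export
fiber_spec <- function(form = c("B", "A"), sequence = "CGCGAATTCGCG", ...) {
  form <- match.arg(form)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2L) stop("sequence must have length >= 2")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("unsupported characters in sequence (need A/C/G/T)")
  }
  par <- .fiber_forms[[form]]
  dots <- list(...)
  unknown <- setdiff(names(dots), names(par))
  if (length(unknown)) {
    stop("unknown fiber parameter(s): ", paste(unknown, collapse = ", "))
  }
  par[names(dots)] <- dots
  structure(c(list(form = form, sequence = bases), par),
            class = "fiber_spec")
}

## Five-membered ring with prescribed Altona-Sundaralingam (P, tau_m),
## built from a regular pentagon with out-of-plane displacements
## z_k = a * cos(phi + 4*pi*k/5) and Newton-refined so that the measured
## pseudorotation of the resulting endocyclic torsions matches the target.
## Atom order: C1', C2', C3', C4', O4'.
.pucker_ring <- function(P, tau_m, bond = 1.48) {
  r <- bond / (2 * sin(pi / 5))
  k <- 0:4
  theta <- deg2rad(90 - k * 72)  # clockwise ordering fixes ring chirality
  measure <- function(par) {
    z <- par[2] * cos(deg2rad(par[1]) + 4 * pi * k / 5)
    xyz <- cbind(r * cos(theta), r * sin(theta), z)
    rownames(xyz) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
    nu <- c(
      dihedral_angle(xyz[4, ], xyz[5, ], xyz[1, ], xyz[2, ]),
      dihedral_angle(xyz[5, ], xyz[1, ], xyz[2, ], xyz[3, ]),
      dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ]),
      dihedral_angle(xyz[2, ], xyz[3, ], xyz[4, ], xyz[5, ]),
      dihedral_angle(xyz[3, ], xyz[4, ], xyz[5, ], xyz[1, ]))
    ps <- pseudorotation(nu)
    list(xyz = xyz, P = ps$P, tau_m = ps$tau_m)
  }
  par <- c(P, tau_m / 102.5 * 0.4)  # rough amplitude scale, refined below
  m0 <- measure(par)
  par[1] <- par[1] + angle_diff(P, m0$P)  # absorb the constant phase offset
  for (it in 1:50) {
    m <- measure(par)
    err <- c(angle_diff(P, m$P), tau_m - m$tau_m)
    if (max(abs(err)) < 1e-10) break
    eps <- c(1e-5, 1e-7)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      pj <- par; pj[j] <- pj[j] + eps[j]
      mj <- measure(pj)
      J[, j] <- c(angle_diff(mj$P, m$P), mj$tau_m - m$tau_m) / eps[j]
    }
    par <- par + solve(J, err)
  }
  m <- measure(par)
  if (max(abs(c(angle_diff(P, m$P), tau_m - m$tau_m))) > 1e-8) {
    stop("ring pucker solver did not converge")
  }
  m$xyz
}

## Direction (unit vector) from a center making prescribed angles with two
## known unit substituent directions; `branch` selects the chiral solution.
.direction_two_angles <- function(d1, d2, ang1_deg, ang2_deg, branch = 1) {
  c1 <- cos(deg2rad(ang1_deg)); c2 <- cos(deg2rad(ang2_deg))
  g <- sum(d1 * d2)
  # v = a d1 + b d2 + c (d1 x d2)
  ab <- solve(matrix(c(1, g, g, 1), 2, 2), c(c1, c2))
  vp <- ab[1] * d1 + ab[2] * d2
  w <- cross3(d1, d2)
  rem <- 1 - sum(vp * vp)
  if (rem < 0) stop("incompatible angle constraints")
  vp + branch * sqrt(rem / sum(w * w)) * w
}

## Deoxyribose + phosphate grown onto a standard base (local base-frame
## coordinates). Returns a matrix of sugar/backbone atoms.
.sugar_local <- function(base, P, tau_m, chi, gamma, beta,
                         chirality = 1, c5_branch = 1, o3_branch = -1) {
  b <- .normalize_base(base)
  std <- .std_bases[[b]]
  n_name <- if (b %in% c("A", "G")) "N9" else "N1"
  cref_name <- if (b %in% c("A", "G")) "C4" else "C2"
  c1_t <- std["C1'", ]
  n_t <- std[n_name, ]
  cref_t <- std[cref_name, ]
  ring <- .pucker_ring(P, tau_m)
  glyco_len <- vnorm(n_t - c1_t)
  # virtual glycosidic nitrogen in ring-local coordinates
  d_o4 <- unitv(ring["O4'", ] - ring["C1'", ])
  d_c2 <- unitv(ring["C2'", ] - ring["C1'", ])
  v_n <- .direction_two_angles(d_o4, d_c2, 108.2, 113.4, branch = chirality)
  n_local <- ring["C1'", ] + glyco_len * v_n
  # target O4' from the glycosidic torsion chi = tors(O4', C1', N, Cref)
  o4_target <- nerf_place(cref_t, n_t, c1_t,
                          vnorm(ring["O4'", ] - ring["C1'", ]), 108.2, chi)
  fitk <- kabsch(rbind(ring["C1'", ], n_local, ring["O4'", ]),
                 rbind(c1_t, n_t, o4_target))
  place <- function(m) sweep(m %*% t(fitk$R), 2, fitk$t, "+")
  ring_t <- place(ring)
  # exocyclic backbone: C5' on C4', O3' on C3' (tetrahedral branches),
  # then O5' and P by the planted gamma and beta torsions
  td <- tetrahedral_directions(unitv(ring_t["C3'", ] - ring_t["C4'", ]),
                               unitv(ring_t["O4'", ] - ring_t["C4'", ]))
  c5 <- ring_t["C4'", ] + 1.51 * unitv(if (c5_branch > 0) td$plus else td$minus)
  td3 <- tetrahedral_directions(unitv(ring_t["C2'", ] - ring_t["C3'", ]),
                                unitv(ring_t["C4'", ] - ring_t["C3'", ]))
  o3 <- ring_t["C3'", ] + 1.42 * unitv(if (o3_branch > 0) td3$plus else td3$minus)
  o5 <- nerf_place(ring_t["C3'", ], ring_t["C4'", ], c5, 1.44, 110.5, gamma)
  p <- nerf_place(ring_t["C4'", ], c5, o5, 1.595, 120.5, beta)
  out <- rbind(P = p, `O5'` = o5, `C5'` = c5, ring_t, `O3'` = o3)
  out
}

#' Build an idealized fiber-model duplex
#'
#' Assembles Cartesian coordinates for an ideal A- or B-form DNA duplex
#' from a [fiber_spec()]: base-pair frames are generated along a straight
#' helical axis with the planted helical parameters, standard Watson-Crick
#' bases are placed on each frame (strand 2 on the flipped frame), and each
#' nucleotide receives a deoxyribose/phosphate backbone with the planted
#' sugar pucker and glycosidic angle. Analyzing the result with
#' [duplex_report()] / [helical_parameters()] round-trips the planted
#' parameters; all A-form sugars classify N and all B-form sugars S.
#'
#' @param spec a [fiber_spec()] (or a form letter, passed to `fiber_spec()`).
#' @param file optional path; when given, coordinates are also written as a
#'   PDB file via `bio3d::write.pdb`.
#' @param sequence used when `spec` is a form letter.
#' @return object of class `"fiber_duplex"`: list with `atoms` (data frame
#'   chain, resno, resid, elety, x, y, z), `pair_frames` (list of strand-1
#'   `"base_frame"`s per pair), `pairing` (data frame of paired residues)
#'   and `truth` (the planted parameters).
#' @export
build_fiber_duplex <- function(spec = fiber_spec("B"), file = NULL,
                               sequence = "CGCGAATTCGCG") {
  if (is.character(spec)) spec <- fiber_spec(spec, sequence = sequence)
  stopifnot(inherits(spec, "fiber_spec"))
  n <- length(spec$sequence)
  d0 <- c(spec$x_displacement, spec$y_displacement, 0)
  tilt0 <- rotation_matrix(c(1, 0, 0), spec$inclination) %*%
    rotation_matrix(c(0, 1, 0), -spec$tip)
  pair_frame <- function(i) {
    Rz <- rotation_matrix(c(0, 0, 1), (i - 1) * spec$htwist)
    make_frame(as.vector(Rz %*% d0) + c(0, 0, (i - 1) * spec$hrise),
               Rz %*% tilt0)
  }
  frames <- lapply(seq_len(n), pair_frame)
  atoms <- list()
  emit <- function(chain, resno, base, frame) {
    b <- .normalize_base(base)
    std <- .std_bases[[b]]
    sugar <- .sugar_local(b, spec$P, spec$tau_m, spec$chi,
                          spec$gamma, spec$beta)
    loc <- rbind(sugar, std[setdiff(rownames(std), "C1'"), , drop = FALSE])
    lab <- sweep(loc %*% t(frame$axes), 2, frame$origin, "+")
    data.frame(chain = chain, resno = resno, resid = paste0("D", b),
               elety = rownames(loc), x = lab[, 1], y = lab[, 2],
               z = lab[, 3], stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    b1 <- spec$sequence[i]
    atoms[[length(atoms) + 1L]] <- emit("A", i, b1, frames[[i]])
    atoms[[length(atoms) + 1L]] <-
      emit("B", n + 1L - i, .complement[[b1]], flip_frame(frames[[i]]))
  }
  atoms <- do.call(rbind, atoms)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  out <- structure(list(
    atoms = atoms,
    pair_frames = frames,
    pairing = data.frame(chain1 = "A", resno1 = seq_len(n),
                         chain2 = "B", resno2 = n:1),
    truth = spec), class = "fiber_duplex")
  if (!is.null(file)) write_duplex_pdb(out, file)
  out
}

#' Write a built duplex to a PDB file
#'
#' @param duplex a `"fiber_duplex"`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_duplex_pdb <- function(duplex, file) {
  stopifnot(inherits(duplex, "fiber_duplex"))
  a <- duplex$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, eleno = seq_len(nrow(a)))
  invisible(file)
}

#' @export
print.fiber_duplex <- function(x, ...) {
  cat(sprintf("fiber duplex: %s-form, %d bp, %d atoms\n", x$truth$form,
              length(x$truth$sequence), nrow(x$atoms)))
  invisible(x)
}
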