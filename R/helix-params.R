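## ---------------------------------------------------------------------------
## CEHS mid-frame algebra. Both base-pair and step parameters derive from the
## same symmetric construction: merge the two frame z-axes by rotating each
## half-way about their mutual hinge, measure the twist about the merged
## z-axis, and express the origin displacement in the mid-frame. The bending
## angle is decomposed into tilt (about the mid-frame x) and roll (about y)
## through the hinge phase.
## ---------------------------------------------------------------------------

.clamp1 <- function(x) pmin(pmax(x, -1), 1)

.step_core <- function(f1, f2) {
  R1 <- f1$axes; R2 <- f2$axes
  o1 <- f1$origin; o2 <- f2$origin
  z1 <- R1[, 3]; z2 <- R2[, 3]
  gamma <- rad2deg(acos(.clamp1(sum(z1 * z2))))
  cr <- cross3(z1, z2)
  if (vnorm(cr) > 1e-9) {
    h <- unitv(cr)
    R1p <- rotation_matrix(h, gamma / 2) %*% R1
    R2p <- rotation_matrix(h, -gamma / 2) %*% R2
  } else {
    h <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- R1p[, 3]
  x1 <- R1p[, 1]; x2 <- R2p[, 1]
  omega <- rad2deg(atan2(sum(cross3(x1, x2) * zm), sum(x1 * x2)))
  xm <- as.vector(rotation_matrix(zm, omega / 2) %*% x1)
  ym <- cross3(zm, xm)
  Rm <- cbind(xm, ym, zm)
  disp <- as.vector(t(Rm) %*% (o2 - o1))
  if (is.null(h)) {
    tilt <- 0; roll <- 0
  } else {
    tilt <- gamma * sum(h * xm)
    roll <- gamma * sum(h * ym)
  }
  list(params = c(shift = disp[1], slide = disp[2], rise = disp[3],
                  tilt = tilt, roll = roll, twist = omega),
       mid = make_frame((o1 + o2) / 2, Rm))
}

#' Base-pair step parameters (CEHS mid-frame construction)
#'
#' Translational (shift, slide, rise; angstrom) and rotational (tilt, roll,
#' twist; degrees) parameters between two base-pair frames, via the standard
#' CEHS/3DNA mid-frame scheme: the two pair z-axes are merged by rotating
#' each half of their mutual bending angle about the hinge axis, twist is
#' the rotation about the merged z-axis, the origin displacement is read in
#' the mid-frame, and the bending angle is decomposed into tilt/roll by the
#' hinge phase. Coincident frames give the identity step (all zeros).
#'
#' @param f1,f2 `"base_frame"` objects for consecutive base pairs (5' to 3'
#'   on strand 1).
#' @return named numeric vector `shift, slide, rise, tilt, roll, twist`,
#'   with the mid-step frame attached as attribute `"mid_frame"`.
#' @seealso [build_step()] for the exact inverse, [helical_parameters()].
#' @export
step_parameters <- function(f1, f2) {
  stopifnot(inherits(f1, "base_frame"), inherits(f2, "base_frame"))
  core <- .step_core(f1, f2)
  structure(core$params, mid_frame = core$mid)
}

#' Rebuild the second frame of a step from parameters
#'
#' Exact inverse of [step_parameters()]: given the first frame and the six
#' step parameters, reconstructs the second frame such that
#' `step_parameters(f1, build_step(f1, p))` returns `p` to numerical
#' precision. Used by the rebuild oracle tests and the fiber builder.
#'
#' @param f1 a `"base_frame"`.
#' @param params named vector with `shift, slide, rise, tilt, roll, twist`.
#' @return the reconstructed `"base_frame"` `f2`.
#' @export
build_step <- function(f1, params) {
  stopifnot(inherits(f1, "base_frame"))
  p <- params[c("shift", "slide", "rise", "tilt", "roll", "twist")]
  if (anyNA(p)) stop("'params' must name shift, slide, rise, tilt, roll, twist")
  R1 <- f1$axes; o1 <- f1$origin
  gamma <- sqrt(p[["tilt"]]^2 + p[["roll"]]^2)
  omega <- p[["twist"]]
  if (gamma > 1e-12) {
    theta <- rad2deg(atan2(p[["roll"]], p[["tilt"]])) + omega / 2
    h <- cos(deg2rad(theta)) * R1[, 1] + sin(deg2rad(theta)) * R1[, 2]
    Qh <- rotation_matrix(h, gamma / 2)
  } else {
    Qh <- diag(3)
  }
  zm <- as.vector(Qh %*% R1[, 3])
  xm <- as.vector(rotation_matrix(zm, omega / 2) %*% (Qh %*% R1[, 1]))
  ym <- cross3(zm, xm)
  R2 <- Qh %*% rotation_matrix(zm, omega) %*% Qh %*% R1
  o2 <- o1 + p[["shift"]] * xm + p[["slide"]] * ym + p[["rise"]] * zm
  make_frame(o2, R2)
}

#' Intra-base-pair parameters
#'
#' Shear, stretch, stagger (angstrom) and buckle, propeller, opening
#' (degrees) of a Watson-Crick pair, computed with the same mid-frame
#' algebra as [step_parameters()] after flipping the strand-2 frame
#' ([flip_frame()]); the transformation runs from the flipped strand-2 frame
#' to the strand-1 frame, so an ideal pair built from coincident frames has
#' all parameters zero. The pair mean frame (used for step parameters) is
#' attached as attribute `"pair_frame"`.
#'
#' @param f1 strand-1 base frame.
#' @param f2 strand-2 base frame (unflipped).
#' @return named numeric vector `shear, stretch, stagger, buckle, propeller,
#'   opening`, with attribute `"pair_frame"`.
#' @export
pair_parameters <- function(f1, f2) {
  stopifnot(inherits(f1, "base_frame"), inherits(f2, "base_frame"))
  core <- .step_core(flip_frame(f2), f1)
  p <- core$params
  structure(c(shear = unname(p["shift"]), stretch = unname(p["slide"]),
              stagger = unname(p["rise"]), buckle = unname(p["tilt"]),
              propeller = unname(p["roll"]), opening = unname(p["twist"])),
            pair_frame = core$mid)
}

## Helical decomposition of one frame against the helical axis u:
## align the frame z with u, read inclination/tip from the axis direction in
## frame coordinates, and locate the axis point in the frame's plane.
.helical_one <- function(f, u, omega_rad, delta, second = FALSE) {
  R <- f$axes; o <- f$origin
  um <- as.vector(t(R) %*% u)
  s2 <- sqrt(um[1]^2 + um[2]^2)
  A <- rad2deg(acos(.clamp1(um[3])))
  if (s2 > 1e-12) {
    incl <- A * um[2] / s2
    tip <- -A * um[1] / s2
    k <- unitv(cross3(R[, 3], u))
    Rh <- rotation_matrix(k, A) %*% R
  } else {
    incl <- 0; tip <- 0
    Rh <- R
  }
  # axis point in the plane through o perpendicular to u
  dperp <- delta - sum(delta * u) * u
  e1 <- Rh[, 1]; e2 <- Rh[, 2]
  # delta_perp = (Rot - I) v for the leading frame (v = origin minus axis
  # point); for the trailing frame delta_perp = (I - Rot^-1) v.
  M <- if (second) {
    matrix(c(1 - cos(omega_rad), -sin(omega_rad),
             sin(omega_rad), 1 - cos(omega_rad)), 2, 2, byrow = TRUE)
  } else {
    matrix(c(cos(omega_rad) - 1, -sin(omega_rad),
             sin(omega_rad), cos(omega_rad) - 1), 2, 2, byrow = TRUE)
  }
  d2 <- c(sum(dperp * e1), sum(dperp * e2))
  if (abs(det(M)) > 1e-12) {
    v2 <- solve(M, d2)  # coordinates of (o - axis point)
    xdisp <- v2[1]
    ydisp <- v2[2]
  } else {
    xdisp <- NA_real_
    ydisp <- NA_real_
  }
  list(incl = incl, tip = tip, xdisp = xdisp, ydisp = ydisp, Rh = Rh)
}

#' Local helical parameters of a base-pair step
#'
#' Helical-axis description of the same step transform used by
#' [step_parameters()]: the local helical axis is the rotation axis carrying
#' frame 1 into frame 2. `htwist` is the rotation about that axis between
#' the axis-aligned frames, `hrise` the origin displacement along it.
#' Inclination and tip measure the orientation of each pair relative to the
#' axis, and x-/y-displacement locate the pair origin relative to the axis
#' point in the pair's own helically aligned frame; the per-pair values of
#' the two pairs forming the step are averaged. On an ideal regular helix
#' this construction returns the generating parameters exactly. A pure
#' twist step about the shared z-axis has zero x-displacement and zero
#' inclination.
#'
#' @param f1,f2 consecutive base-pair `"base_frame"`s.
#' @return named numeric vector `x_displacement, y_displacement, hrise,
#'   inclination, tip, htwist` (angstrom / degrees). `x_displacement` is
#'   `NA` for a twist-free step (no axis point defined).
#' @export
helical_parameters <- function(f1, f2) {
  stopifnot(inherits(f1, "base_frame"), inherits(f2, "base_frame"))
  R <- f2$axes %*% t(f1$axes)
  skew <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- vnorm(skew) / 2
  cosang <- (sum(diag(R)) - 1) / 2
  if (s > 1e-12) {
    u <- skew / (2 * s)
  } else {
    u <- f1$axes[, 3]  # no net rotation: axis degenerate, use pair normal
  }
  ang <- rad2deg(atan2(s, cosang))
  if (sum(u * (f1$axes[, 3] + f2$axes[, 3])) < 0) {
    u <- -u
    ang <- -ang
  }
  delta <- f2$origin - f1$origin
  hrise <- sum(delta * u)
  h1 <- .helical_one(f1, u, deg2rad(ang), delta)
  h2 <- .helical_one(f2, u, deg2rad(ang), delta, second = TRUE)
  # twist about the axis between the axis-aligned frames
  x1h <- h1$Rh[, 1]; x2h <- h2$Rh[, 1]
  htwist <- rad2deg(atan2(sum(cross3(x1h, x2h) * u), sum(x1h * x2h)))
  c(x_displacement = mean(c(h1$xdisp, h2$xdisp)),
    y_displacement = mean(c(h1$ydisp, h2$ydisp)),
    hrise = hrise,
    inclination = mean(c(h1$incl, h2$incl)),
    tip = mean(c(h1$tip, h2$tip)),
    htwist = htwist)
}

#' Groove widths from phosphate positions
#'
#' Cross-strand phosphorus-phosphorus distance minima following the
#' El Hassan-Calladine prescription: at each level the minor-groove width is
#' the shortest P-P distance to the opposite strand a few residues toward
#' its 3' end, the major-groove width the shortest distance in the opposite
#' direction, each reduced by twice the phosphate group radius (5.8
#' angstrom). Levels are indexed in the 5'-to-3' frame of strand 1.
#'
#' @param p1 matrix of strand-1 phosphorus coordinates, 5' to 3' (rows).
#' @param p2 matrix of strand-2 phosphorus coordinates, 5' to 3' of strand
#'   2 (rows); internally reversed so row i faces `p1` row i.
#' @param radius_correction subtracted constant, default 5.8 angstrom.
#' @param minor_offsets,major_offsets index offsets (on the reversed strand
#'   2) searched for the minimum in each groove direction.
#' @param interior_only drop levels whose offset windows run off either
#'   strand end instead of clipping them.
#' @return data frame `level, minor, major` (angstrom) with attribute
#'   `"means"` = mean over reported levels.
#' @export
groove_widths <- function(p1, p2, radius_correction = 5.8,
                          minor_offsets = -(2:4), major_offsets = 0:3,
                          interior_only = TRUE) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  if (nrow(p1) < 4L || nrow(p2) < 4L) {
    stop("groove widths need >= 4 phosphates per strand")
  }
  q <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
  n1 <- nrow(p1); n2 <- nrow(q)
  lev <- seq_len(n1)
  one <- function(i, offs) {
    j <- i + offs
    j <- j[j >= 1 & j <= n2]
    if (length(j) < length(offs) && interior_only) return(NA_real_)
    if (length(j) == 0L) return(NA_real_)
    min(sqrt(rowSums((q[j, , drop = FALSE] -
                        matrix(p1[i, ], length(j), 3, byrow = TRUE))^2))) -
      radius_correction
  }
  minor <- vapply(lev, one, numeric(1), offs = minor_offsets)
  major <- vapply(lev, one, numeric(1), offs = major_offsets)
  out <- data.frame(level = lev, minor = minor, major = major)
  out <- out[!(is.na(out$minor) & is.na(out$major)), , drop = FALSE]
  attr(out, "means") <- c(minor = mean(out$minor, na.rm = TRUE),
                          major = mean(out$major, na.rm = TRUE))
  out
}
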