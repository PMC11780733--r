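## ---------------------------------------------------------------------------
## Standard base geometries in the standard (Olson-convention) base reference
## frame: x toward the major groove along the pseudo-dyad, y along the long
## axis toward the sugar, z normal to the base plane, origin at the pair
## centre. In this convention the frame of the complementary base in an ideal
## Watson-Crick pair is the same frame with its y and z axes negated, which is
## exactly how the fiber builder and the pairing algebra use it.
## ---------------------------------------------------------------------------

.std_bases <- list(
  A = matrix(c(
    -2.477,  5.399, 0.000,   # C1'
    -1.291,  4.498, 0.000,   # N9
     0.024,  4.897, 0.000,   # C8
     0.877,  3.902, 0.000,   # N7
     0.071,  2.771, 0.000,   # C5
     0.369,  1.398, 0.000,   # C6
     1.611,  0.909, 0.000,   # N6
    -0.668,  0.532, 0.000,   # N1
    -1.912,  1.023, 0.000,   # C2
    -2.320,  2.290, 0.000,   # N3
    -1.267,  3.124, 0.000),  # C4
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1",
                      "C2", "N3", "C4"), NULL)),
  G = matrix(c(
    -2.477,  5.399, 0.000,
    -1.289,  4.551, 0.000,   # N9
     0.023,  4.962, 0.000,   # C8
     0.870,  3.969, 0.000,   # N7
     0.071,  2.833, 0.000,   # C5
     0.424,  1.460, 0.000,   # C6
     1.554,  0.955, 0.000,   # O6
    -0.700,  0.641, 0.000,   # N1
    -1.999,  1.087, 0.000,   # C2
    -2.949,  0.139, 0.000,   # N2
    -2.342,  2.364, 0.000,   # N3
    -1.265,  3.177, 0.000),  # C4
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1",
                      "C2", "N2", "N3", "C4"), NULL)),
  C = matrix(c(
    -2.477,  5.399, 0.000,
    -1.285,  4.542, 0.000,   # N1
    -1.472,  3.158, 0.000,   # C2
    -2.628,  2.709, 0.000,   # O2
    -0.391,  2.344, 0.000,   # N3
     0.837,  2.868, 0.000,   # C4
     1.875,  2.027, 0.000,   # N4
     1.056,  4.275, 0.000,   # C5
    -0.023,  5.068, 0.000),  # C6
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5",
                      "C6"), NULL)),
  T = matrix(c(
    -2.477,  5.399, 0.000,
    -1.284,  4.500, 0.000,   # N1
    -1.462,  3.135, 0.000,   # C2
    -2.562,  2.608, 0.000,   # O2
    -0.298,  2.407, 0.000,   # N3
     0.994,  2.897, 0.000,   # C4
     1.944,  2.119, 0.000,   # O4
     1.106,  4.338, 0.000,   # C5
     2.466,  4.961, 0.000,   # C7
    -0.024,  5.057, 0.000),  # C6
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5",
                      "C7", "C6"), NULL)),
  U = matrix(c(
    -2.477,  5.399, 0.000,
    -1.284,  4.500, 0.000,   # N1
    -1.462,  3.131, 0.000,   # C2
    -2.563,  2.608, 0.000,   # O2
    -0.302,  2.397, 0.000,   # N3
     0.989,  2.884, 0.000,   # C4
     1.935,  2.094, 0.000,   # O4
     1.089,  4.311, 0.000,   # C5
    -0.024,  5.053, 0.000),  # C6
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5",
                      "C6"), NULL))
)

.ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.complement <- c(A = "T", T = "A", G = "C", C = "G", U = "A")

.normalize_base <- function(base) {
  b <- toupper(sub("^D", "", base))
  if (!b %in% names(.std_bases)) stop(sprintf("unsupported base '%s'", base))
  b
}

#' Standard base geometry in the standard reference frame
#'
#' Idealized planar base coordinates embedded in the standard base reference
#' frame (origin at the Watson-Crick pair centre, x toward the major groove,
#' y toward the sugar of the owning strand, z normal to the base plane).
#' These embedded geometries are the templates fitted by [base_frame()] and
#' the bases placed by [build_fiber_duplex()].
#'
#' @param base one of `"A"`, `"G"`, `"C"`, `"T"`, `"U"` (a leading `"D"` as
#'   in PDB residue names `DA` etc. is accepted).
#' @param ring_only return only the base ring atoms used for frame fitting.
#' @return numeric matrix of coordinates (angstrom) with atom-name rownames.
#' @export
standard_base <- function(base, ring_only = FALSE) {
  b <- .normalize_base(base)
  m <- .std_bases[[b]]
  if (ring_only) m[.ring_atoms[[b]], , drop = FALSE] else m
}

#' Base reference frame from observed coordinates
#'
#' Least-squares rigid superposition (Kabsch) of the embedded standard base
#' ring onto the observed ring atoms. The returned frame is the transformed
#' standard frame: `axes` is the rotation (columns are the frame x, y, z
#' axes in laboratory coordinates) and `origin` the transformed standard
#' origin. At least three ring atoms must be present; both purine and
#' pyrimidine atom sets are supported.
#'
#' @param xyz numeric matrix of observed coordinates with atom-name rownames
#'   (primed or starred sugar names are irrelevant here; only base ring
#'   atom names are used).
#' @param base base identity, see [standard_base()].
#' @return list of class `"base_frame"` with `origin` (length-3), `axes`
#'   (3x3 rotation, right-handed orthonormal) and `fit_rmsd` (angstrom).
#' @export
base_frame <- function(xyz, base) {
  b <- .normalize_base(base)
  ring <- .ring_atoms[[b]]
  have <- intersect(ring, rownames(xyz))
  if (length(have) < 3L) {
    stop(sprintf("base_frame needs >= 3 of the ring atoms %s; found %d",
                 paste(ring, collapse = ","), length(have)))
  }
  std <- .std_bases[[b]][have, , drop = FALSE]
  obs <- xyz[have, , drop = FALSE]
  k <- kabsch(std, obs)
  structure(list(origin = as.vector(k$t), axes = k$R, fit_rmsd = k$rmsd),
            class = "base_frame")
}

#' Construct a base frame from an origin and axes
#'
#' Low-level constructor used by the fiber builder and the rebuild oracle;
#' validates orthonormality and handedness.
#'
#' @param origin length-3 numeric.
#' @param axes 3x3 rotation matrix, columns = frame axes.
#' @return a `"base_frame"` object.
#' @export
make_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (max(abs(t(axes) %*% axes - diag(3))) > 1e-9 ||
      abs(det(axes) - 1) > 1e-9) {
    stop("'axes' must be a right-handed orthonormal triad")
  }
  structure(list(origin = as.numeric(origin), axes = axes,
                 fit_rmsd = 0), class = "base_frame")
}

#' Flip a base frame to the opposite strand convention
#'
#' Negates the y and z axes (a proper 180-degree rotation about x). The
#' frame of the complementary base of an ideal Watson-Crick pair is the
#' pair frame flipped this way, and pairing algebra flips the strand-2
#' frame before computing intra-pair parameters.
#'
#' @param f a `"base_frame"`.
#' @return the flipped `"base_frame"`.
#' @export
flip_frame <- function(f) {
  stopifnot(inherits(f, "base_frame"))
  make_frame(f$origin, f$axes %*% diag(c(1, -1, -1)))
}

#' @export
print.base_frame <- function(x, ...) {
  cat(sprintf("base frame: origin (%.3f, %.3f, %.3f), fit rmsd %.4f A\n",
              x$origin[1], x$origin[2], x$origin[3], x$fit_rmsd))
  invisible(x)
}
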