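#' Fourier dihedral term and torsion type constructors
#'
#' An AMBER dihedral is a sum of cosine terms
#' \eqn{E(\phi) = \sum_n \frac{V_n/2}{\mathrm{IDIVF}}
#'      \left[1 + \cos(n\phi - \gamma_n)\right]},
#' each term carrying a periodicity \eqn{n}, a half barrier \eqn{V_n/2}
#' (kcal/mol), a phase \eqn{\gamma_n} (degrees) and the frcmod divider
#' IDIVF. A `torsion_type` attaches a list of such terms to an ordered
#' atom-type quadruple; quadruple matching is palindromic
#' (A-B-C-D is the same type as D-C-B-A).
#'
#' @param periodicity integer periodicity, 1-6.
#' @param half_barrier \eqn{V_n/2} in kcal/mol.
#' @param phase phase \eqn{\gamma} in degrees.
#' @param divider frcmod IDIVF divider, integer >= 1.
#' @return `fourier_term()`: a list of class `"fourier_term"`;
#'   `torsion_type()`: a list of class `"torsion_type"` with elements
#'   `atom_types` and `terms`.
#' @export
fourier_term <- function(periodicity, half_barrier, phase = 0, divider = 1L) {
  periodicity <- as.integer(periodicity)
  divider <- as.integer(divider)
  stopifnot(periodicity >= 1L, periodicity <= 6L, divider >= 1L,
            is.finite(half_barrier), is.finite(phase))
  structure(list(periodicity = periodicity, half_barrier = half_barrier,
                 phase = phase, divider = divider),
            class = "fourier_term")
}

#' @param atom_types character vector of four AMBER atom-type labels.
#' @param terms list of [fourier_term()] objects (at least one).
#' @rdname fourier_term
#' @export
torsion_type <- function(atom_types, terms) {
  stopifnot(length(atom_types) == 4L, length(terms) >= 1L)
  stopifnot(all(vapply(terms, inherits, logical(1), "fourier_term")))
  structure(list(atom_types = as.character(atom_types), terms = terms),
            class = "torsion_type")
}

#' Test whether two atom-type quadruples name the same torsion type
#'
#' Matching is palindromic: `A-B-C-D` matches both `A-B-C-D` and `D-C-B-A`.
#' @param a,b character vectors of four atom-type labels.
#' @return logical scalar.
#' @export
same_torsion_type <- function(a, b) {
  identical(as.character(a), as.character(b)) ||
    identical(as.character(a), rev(as.character(b)))
}

#' AMBER-style dihedral energy
#'
#' Evaluates \eqn{E(\phi) = \sum_n \frac{V_n/2}{\mathrm{IDIVF}}
#' [1 + \cos(n\phi - \gamma_n)]} for one torsion type. The value is exactly
#' the term sum; no sign constraint is implied.
#'
#' @param tt a [torsion_type()].
#' @param phi dihedral angle(s) in degrees (vectorized).
#' @return energy in kcal/mol, same length as `phi`.
#' @export
#' @examples
#' tt <- torsion_type(c("CT", "CT", "CT", "CT"),
#'                    list(fourier_term(2, 1.0, 180)))
#' dihedral_energy(tt, 90)  # 2.0
dihedral_energy <- function(tt, phi) {
  stopifnot(inherits(tt, "torsion_type"))
  e <- numeric(length(phi))
  for (tm in tt$terms) {
    e <- e + (tm$half_barrier / tm$divider) *
      (1 + cos(deg2rad(tm$periodicity * phi - tm$phase)))
  }
  e
}

## ---------------------------------------------------------------------------
## frcmod dialect I/O. Only the DIHE block is interpreted; MASS/BOND/ANGLE/
## IMPROPER/NONBON blocks are carried through verbatim. Multi-term dihedrals
## use the AMBER continuation convention: every term except the last carries
## a negative periodicity.
## ---------------------------------------------------------------------------

.frcmod_blocks <- c("MASS", "BOND", "ANGLE", "DIHE", "IMPROPER", "NONBON")

#' Read an AMBER frcmod parameter file
#'
#' Parses the frcmod dialect (title line, then MASS/BOND/ANGLE/DIHE/IMPROPER/
#' NONBON blocks separated by blank lines). Only the DIHE block is
#' interpreted, into [torsion_type()] objects; all other blocks are kept
#' verbatim and re-emitted unchanged by [write_frcmod()]. On read, whitespace-
#' separated fields are accepted; [write_frcmod()] emits canonical spacing, so
#' read-write-read is a fixed point and the written DIHE block is byte-stable.
#'
#' @param file path to an frcmod file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `file`).
#' @return list of class `"frcmod"` with elements `title`, `dihedrals`
#'   (list of `torsion_type`) and `blocks` (named list of verbatim lines).
#' @export
read_frcmod <- function(file, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  if (length(lines) == 0L) stop("empty frcmod input")
  title <- lines[1]
  blocks <- list()
  current <- NULL
  block_lines <- list()
  line_no <- integer(0)
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    key <- toupper(trimws(ln))
    key <- sub("^(DIHE)DRAL$", "\\1", key)
    if (key %in% .frcmod_blocks) {
      current <- key
      block_lines[[current]] <- character(0)
      line_no[[current]] <- i
      next
    }
    if (is.null(current) || !nzchar(trimws(ln))) next
    block_lines[[current]] <- c(block_lines[[current]], ln)
  }
  dihe <- list()
  if (!is.null(block_lines[["DIHE"]])) {
    dihe <- .parse_dihe_block(block_lines[["DIHE"]],
                              first_line = line_no[["DIHE"]] + 1L)
  }
  block_lines[["DIHE"]] <- NULL
  structure(list(title = title, dihedrals = dihe, blocks = block_lines),
            class = "frcmod")
}

.parse_dihe_block <- function(lines, first_line = 1L) {
  types <- list()
  pending_types <- NULL
  pending_terms <- list()
  pat <- "^\\s*(\\S{1,2})\\s*-\\s*(\\S{1,2})\\s*-\\s*(\\S{1,2})\\s*-\\s*(\\S{1,2})\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)"
  for (k in seq_along(lines)) {
    ln <- lines[k]
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed DIHE line %d: '%s'", first_line + k - 1L, ln))
    }
    at <- m[2:5]
    idivf <- suppressWarnings(as.integer(as.numeric(m[6])))
    pk <- suppressWarnings(as.numeric(m[7]))
    phase <- suppressWarnings(as.numeric(m[8]))
    pn <- suppressWarnings(as.numeric(m[9]))
    if (anyNA(c(idivf, pk, phase, pn))) {
      stop(sprintf("malformed DIHE line %d: non-numeric field in '%s'",
                   first_line + k - 1L, ln))
    }
    if (!is.null(pending_types) && !same_torsion_type(pending_types, at)) {
      stop(sprintf(
        "malformed DIHE line %d: continuation term for %s but found type %s",
        first_line + k - 1L, paste(pending_types, collapse = "-"),
        paste(at, collapse = "-")))
    }
    pending_types <- if (is.null(pending_types)) at else pending_types
    pending_terms <- c(pending_terms,
                       list(fourier_term(abs(pn), pk, phase, idivf)))
    if (pn > 0) {  # last term of this dihedral
      types <- c(types, list(torsion_type(pending_types, pending_terms)))
      pending_types <- NULL
      pending_terms <- list()
    }
  }
  if (!is.null(pending_types)) {
    stop("malformed DIHE block: trailing continuation (negative periodicity) term")
  }
  types
}

#' Write an frcmod parameter set
#'
#' Serializes a parsed [read_frcmod()] object (or one assembled in code) back
#' to frcmod text with canonical spacing. The DIHE block is regenerated from
#' the `torsion_type` objects; all other blocks are emitted verbatim.
#'
#' @param x an object of class `"frcmod"`, or a list of `torsion_type`
#'   objects (then a minimal file with only a DIHE block is produced).
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @param title title line used when `x` is a bare list of torsion types.
#' @return character vector of lines, invisibly when written to `file`.
#' @export
write_frcmod <- function(x, file = NULL, title = "dihedral parameter set") {
  if (!inherits(x, "frcmod")) {
    stopifnot(all(vapply(x, inherits, logical(1), "torsion_type")))
    x <- structure(list(title = title, dihedrals = x, blocks = list()),
                   class = "frcmod")
  }
  out <- x$title
  for (blk in .frcmod_blocks) {
    if (blk == "DIHE") {
      out <- c(out, "DIHE", .format_dihe_block(x$dihedrals), "")
    } else if (!is.null(x$blocks[[blk]])) {
      out <- c(out, blk, x$blocks[[blk]], "")
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.format_dihe_block <- function(dihedrals) {
  unlist(lapply(dihedrals, function(tt) {
    nt <- length(tt$terms)
    lab <- paste(sprintf("%-2s", tt$atom_types), collapse = "-")
    vapply(seq_len(nt), function(k) {
      tm <- tt$terms[[k]]
      pn <- if (k < nt) -tm$periodicity else tm$periodicity
      sprintf("%s %4d %12.6f %9.3f %6.1f", lab, tm$divider,
              tm$half_barrier, tm$phase, as.numeric(pn))
    }, character(1))
  }))
}

#' @export
print.frcmod <- function(x, ...) {
  cat(sprintf("frcmod: '%s'\n  %d dihedral type(s); passthrough blocks: %s\n",
              x$title, length(x$dihedrals),
              if (length(x$blocks)) paste(names(x$blocks), collapse = ", ")
              else "none"))
  invisible(x)
}
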