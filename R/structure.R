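## Normalize an atom table out of the accepted inputs: a bio3d pdb object, a
## path to a PDB file, a fiber_duplex from the builder, or a plain data frame
## with columns chain, resno, resid, elety, x, y, z. Alternate locations
## other than blank/'A' are dropped; `model` selects the MODEL of a
## multi-model file (first by default).
.atom_table <- function(x, model = 1) {
  if (inherits(x, "fiber_duplex")) return(x$atoms)
  if (is.character(x) && length(x) == 1L) {
    x <- bio3d::read.pdb(x, multi = TRUE, verbose = FALSE)
  }
  if (inherits(x, "pdb")) {
    at <- x$atom
    if (!is.null(x$xyz) && is.matrix(unclass(x$xyz)) &&
        nrow(unclass(x$xyz)) >= 1) {
      xyz <- unclass(x$xyz)
      if (model > nrow(xyz)) {
        stop(sprintf("model %d requested but file has %d model(s)",
                     model, nrow(xyz)))
      }
      m <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
      at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
    }
    keep <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    return(data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x),
            all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in%
                  names(x)))
  x
}

.norm_elety <- function(e) gsub("\\*", "'", trimws(e))

.is_purine <- function(resname) {
  toupper(sub("^D", "", sub("[35]$", "", trimws(resname)))) %in% c("A", "G")
}

#' Backbone, glycosidic and ring torsions from coordinates
#'
#' Re-implementation of the standard per-residue nucleic-acid dihedral
#' extraction: the seven backbone/glycosidic angles (alpha, beta, gamma,
#' delta, epsilon, zeta, chi; reported in \eqn{[0, 360)}) and the five
#' endocyclic sugar torsions nu0-nu4 (reported in \eqn{[-180, 180)}),
#' plus the pseudorotation phase, amplitude and N/S class for every residue.
#' 5'-terminal residues have undefined alpha (and beta when no phosphate is
#' present); 3'-terminal residues have undefined epsilon/zeta; these are
#' reported as `NA`. Residues missing a required sugar or base atom are
#' skipped with a warning record rather than failing the whole structure.
#'
#' @param x a `bio3d` pdb object, a PDB file path, a [build_fiber_duplex()]
#'   result, or an atom data frame (columns chain, resno, resid, elety,
#'   x, y, z).
#' @param model MODEL number used for multi-model PDB files (default first).
#' @return data frame with one row per analyzable residue: `chain`, `resno`,
#'   `resid`, `is_terminal5`, `is_terminal3`, `alpha` ... `chi`,
#'   `nu0` ... `nu4`, `P`, `tau_m`, `pucker_class`. Skipped residues are
#'   recorded in attribute `"warnings"`.
#' @export
angles_from_structure <- function(x, model = 1) {
  at <- .atom_table(x, model = model)
  at$elety <- .norm_elety(at$elety)
  res_key <- paste(at$chain, at$resno)
  chains <- unique(at$chain)
  rows <- list()
  warns <- character(0)
  for (ch in chains) {
    sel <- at$chain == ch
    resnos <- unique(at$resno[sel])
    resnos <- resnos[order(resnos)]
    coord <- function(rn, name) {
      i <- which(sel & at$resno == rn & at$elety == name)
      if (length(i) == 0L) return(NULL)
      c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
    }
    dihe <- function(p1, p2, p3, p4) {
      if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) {
        return(NA_real_)
      }
      dihedral_angle(p1, p2, p3, p4)
    }
    for (k in seq_along(resnos)) {
      rn <- resnos[k]
      resname <- at$resid[sel & at$resno == rn][1]
      ring_names <- c("O4'", "C1'", "C2'", "C3'", "C4'")
      ring <- lapply(ring_names, coord, rn = rn)
      names(ring) <- ring_names
      if (any(vapply(ring, is.null, logical(1)))) {
        miss <- ring_names[vapply(ring, is.null, logical(1))]
        warns <- c(warns, sprintf(
          "%s %s %d skipped: missing atom(s) %s", ch, resname, rn,
          paste(miss, collapse = ",")))
        next
      }
      nu <- c(
        dihe(ring[["C4'"]], ring[["O4'"]], ring[["C1'"]], ring[["C2'"]]),
        dihe(ring[["O4'"]], ring[["C1'"]], ring[["C2'"]], ring[["C3'"]]),
        dihe(ring[["C1'"]], ring[["C2'"]], ring[["C3'"]], ring[["C4'"]]),
        dihe(ring[["C2'"]], ring[["C3'"]], ring[["C4'"]], ring[["O4'"]]),
        dihe(ring[["C3'"]], ring[["C4'"]], ring[["O4'"]], ring[["C1'"]]))
      ps <- pseudorotation(nu)
      p5 <- coord(rn, "P"); o5 <- coord(rn, "O5'"); c5 <- coord(rn, "C5'")
      o3 <- coord(rn, "O3'")
      prev_rn <- if (k > 1L) resnos[k - 1L] else NA
      next_rn <- if (k < length(resnos)) resnos[k + 1L] else NA
      o3_prev <- if (!is.na(prev_rn)) coord(prev_rn, "O3'") else NULL
      p_next <- if (!is.na(next_rn)) coord(next_rn, "P") else NULL
      o5_next <- if (!is.na(next_rn)) coord(next_rn, "O5'") else NULL
      alpha <- dihe(o3_prev, p5, o5, c5)
      beta <- dihe(p5, o5, c5, ring[["C4'"]])
      gamma <- dihe(o5, c5, ring[["C4'"]], ring[["C3'"]])
      delta <- dihe(c5, ring[["C4'"]], ring[["C3'"]], o3)
      epsilon <- dihe(ring[["C4'"]], ring[["C3'"]], o3, p_next)
      zeta <- dihe(ring[["C3'"]], o3, p_next, o5_next)
      if (.is_purine(resname)) {
        chi <- dihe(ring[["O4'"]], ring[["C1'"]], coord(rn, "N9"),
                    coord(rn, "C4"))
      } else {
        chi <- dihe(ring[["O4'"]], ring[["C1'"]], coord(rn, "N1"),
                    coord(rn, "C2"))
      }
      if (is.na(chi)) {
        warns <- c(warns, sprintf(
          "%s %s %d skipped: missing glycosidic atoms", ch, resname, rn))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = rn, resid = resname,
        is_terminal5 = k == 1L, is_terminal3 = k == length(resnos),
        alpha = wrap360(alpha), beta = wrap360(beta), gamma = wrap360(gamma),
        delta = wrap360(delta), epsilon = wrap360(epsilon),
        zeta = wrap360(zeta), chi = wrap360(chi),
        nu0 = nu[1], nu1 = nu[2], nu2 = nu[3], nu3 = nu[4], nu4 = nu[5],
        P = ps$P, tau_m = ps$tau_m, pucker_class = ps$pucker_class,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no analyzable nucleotide residues found")
  rownames(out) <- NULL
  if (length(warns)) {
    for (w in warns) warning(w, call. = FALSE)
  }
  attr(out, "warnings") <- warns
  out
}

#' Read and write delimited angle tables
#'
#' Tab-delimited serialization of the per-residue/per-frame angle tables
#' produced by [angles_from_structure()] and [simulate_pucker_series()].
#'
#' @param x data frame to write.
#' @param file path.
#' @return `read_angle_table()` returns a data frame.
#' @export
write_angle_table <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_angle_table
#' @export
read_angle_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
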