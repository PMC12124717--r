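# Amber-format output: frcmod parameter files, Tripos mol2, PDB (HETATM)
# and a minimal leap OFF library. All writers are byte-deterministic for
# identical inputs and produce text that the package's own readers (and the
# standard tools) re-parse to the printed precision.

# deterministic key order: metal-involving entries first, lexicographic
# within each group
.order_keys <- function(keys, metal_types) {
  if (!length(keys)) return(character(0))
  involves <- vapply(strsplit(keys, "-", fixed = TRUE), function(tt)
    any(tt %in% metal_types), logical(1L))
  keys[order(!involves, keys)]
}

#' Write an Amber frcmod parameter-modification file
#'
#' Emits MASS, BOND, ANGLE, DIHE, IMPROPER and NONBON sections in that
#' order. Bond constants are printed to 3 decimals and equilibrium lengths
#' to 4; angle constants and equilibria to 3; dihedrals carry the IDIVF,
#' PK, PHASE, PN columns with Amber-default 1-4 scaling noted (SCEE 1.2,
#' SCNB 2.0). Bond and angle force constants are the doubled harmonic
#' constants for the Amber `K (x - x0)^2` energy form. Metal-involving
#' entries are written first, then the rest lexicographically, so output is
#' byte-stable across runs.
#'
#' @param params An `"ff_parameter_set"` from [assemble_parameters()].
#' @param path Optional output path.
#' @param title First line of the file.
#' @return The frcmod text, invisibly when `path` is given.
#' @export
write_frcmod <- function(params, path = NULL,
                         title = "metalff parameters (Seminario metal terms, doubled harmonic constants)") {
  stopifnot(inherits(params, "ff_parameter_set"))
  if (!length(params$bonds) && !length(params$angles))
    stop("parameter set is empty: nothing to write", call. = FALSE)
  if (any(nchar(names(params$lj)) > 4L))
    stop("type labels are limited to 4 characters", call. = FALSE)
  mt <- params$metal_types
  lines <- c(title, "MASS")
  for (ty in .order_keys(names(params$masses), mt))
    lines <- c(lines, sprintf("%-4s %10.3f", ty, params$masses[[ty]]))
  lines <- c(lines, "", "BOND")
  for (key in .order_keys(names(params$bonds), mt)) {
    e <- params$bonds[[key]]
    lines <- c(lines, sprintf("%-11s %10.3f %9.4f", key, e$k, e$r_eq))
  }
  lines <- c(lines, "", "ANGLE")
  for (key in .order_keys(names(params$angles), mt)) {
    e <- params$angles[[key]]
    lines <- c(lines, sprintf("%-14s %10.3f %10.3f", key, e$k, e$theta_eq))
  }
  lines <- c(lines, "", "DIHE")
  for (key in .order_keys(names(params$dihedrals), mt)) {
    e <- params$dihedrals[[key]]
    for (term in e$terms)
      lines <- c(lines, sprintf(
        "%-17s %4d %10.3f %10.3f %9.1f    SCEE=1.2 SCNB=2.0",
        key, as.integer(term$idivf), term$pk, term$phase, term$pn))
  }
  lines <- c(lines, "", "IMPROPER", "", "NONBON")
  for (ty in .order_keys(names(params$lj), mt)) {
    e <- params$lj[[ty]]
    lines <- c(lines, sprintf("  %-4s %10.4f %10.4f", ty, e$rmin_half,
                              e$eps))
  }
  lines <- c(lines, "")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(text)) }
  text
}

#' Write a Tripos mol2 file
#'
#' MOLECULE/ATOM/BOND blocks; atom names are element+index, the SYBYL
#' atom-type column carries the package's type labels (ULS labels
#' included), the substructure is a single residue, and the bond list is
#' exactly the perceived bond set (metal bonds included, order 1).
#'
#' @param geom A [geometry()].
#' @param topology A `"topology"`.
#' @param assignment An `"atom_types"`.
#' @param charges Optional [charge_set()]; zeros when absent.
#' @param residue 3-character residue name.
#' @param path Optional output path.
#' @return The mol2 text, invisibly when `path` is given.
#' @export
write_mol2 <- function(geom, topology, assignment, charges = NULL,
                       residue = "LIG", path = NULL) {
  stopifnot(inherits(geom, "geometry"), inherits(topology, "topology"),
            inherits(assignment, "atom_types"))
  n <- geom$n_atoms
  q <- if (is.null(charges)) rep(0, n) else charges$charges
  if (length(q) != n)
    stopf("charge set has %d entries for %d atoms", length(q), n)
  residue <- substr(residue, 1L, 3L)
  lines <- c("@<TRIPOS>MOLECULE", residue,
             sprintf("%5d %5d %5d %5d %5d", n, nrow(topology$bonds),
                     1L, 0L, 0L),
             "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM")
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%7d %-8s %10.4f %10.4f %10.4f %-6s %5d %-8s %12.6f",
      i, paste0(geom$elements[i], i),
      geom$coordinates[i, 1L], geom$coordinates[i, 2L],
      geom$coordinates[i, 3L],
      assignment$types[i], 1L, residue, q[i]))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  for (k in seq_len(nrow(topology$bonds)))
    lines <- c(lines, sprintf("%6d %5d %5d %s", k,
                              topology$bonds[k, 1L], topology$bonds[k, 2L],
                              "1"))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(text)) }
  text
}

#' Write a PDB file (HETATM records)
#'
#' Single-residue HETATM records, coordinates to 3 decimals, element
#' symbols right-justified in columns 77-78; one-letter atom names start in
#' column 14, two-letter elements in column 13 (PDB v3.3 conventions).
#'
#' @param geom A [geometry()].
#' @param residue 3-character residue name.
#' @param path Optional output path.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(geom, residue = "LIG", path = NULL) {
  stopifnot(inherits(geom, "geometry"))
  n <- geom$n_atoms
  if (n > 99999L) stop("PDB supports at most 99999 atoms", call. = FALSE)
  residue <- substr(residue, 1L, 3L)
  lines <- character(n + 1L)
  for (i in seq_len(n)) {
    el <- geom$elements[i]
    name <- paste0(el, i)
    # column 13 for 2-char elements, 14 for 1-char
    name_field <- if (nchar(el) == 2L) sprintf("%-4s", substr(name, 1L, 4L))
      else sprintf(" %-3s", substr(name, 1L, 3L))
    lines[i] <- sprintf(
      "HETATM%5d %s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name_field, residue, 1L,
      geom$coordinates[i, 1L], geom$coordinates[i, 2L],
      geom$coordinates[i, 3L], 1.0, 0.0, toupper(el))
  }
  lines[n + 1L] <- "END"
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(text)) }
  text
}

#' Write a minimal Amber leap library (OFF) entry
#'
#' A reduced OFF-format unit: atoms table (name, type, charge, atomic
#' number) and connectivity. Enough for topology/charge bookkeeping; full
#' leap-internal table fidelity is not attempted.
#'
#' @inheritParams write_mol2
#' @return The library text, invisibly when `path` is given.
#' @export
write_lib <- function(geom, topology, assignment, charges = NULL,
                      residue = "LIG", path = NULL) {
  stopifnot(inherits(geom, "geometry"), inherits(topology, "topology"))
  n <- geom$n_atoms
  q <- if (is.null(charges)) rep(0, n) else charges$charges
  residue <- substr(residue, 1L, 3L)
  lines <- c("!!index array str", sprintf(" \"%s\"", residue),
             sprintf("!entry.%s.unit.atoms table  str name  str type  int typex  int resx  int flags  int seq  int elmnt  dbl chg",
                     residue))
  for (i in seq_len(n))
    lines <- c(lines, sprintf(" \"%s\" \"%s\" 0 1 131072 %d %d %.6f",
                              paste0(geom$elements[i], i),
                              assignment$types[i], i,
                              element_number(geom$elements[i]), q[i]))
  lines <- c(lines,
             sprintf("!entry.%s.unit.connectivity table  int atom1x  int atom2x  int flags",
                     residue))
  for (k in seq_len(nrow(topology$bonds)))
    lines <- c(lines, sprintf(" %d %d 1", topology$bonds[k, 1L],
                              topology$bonds[k, 2L]))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(text)) }
  text
}
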