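# Atom-type assignment: a simple element+coordination heuristic for the
# organic scaffold (with a user override hook), element-symbol types for
# metals, and the unique labeling strategy (ULS) that gives every
# metal-coordinating atom its own atom type so no two chemically distinct
# metal terms collapse onto one parameter entry.

new_atom_types <- function(types, provenance, uls_atoms = integer(0)) {
  structure(list(types = types, provenance = provenance,
                 uls_atoms = sort(uls_atoms)),
            class = "atom_types")
}

#' @export
print.atom_types <- function(x, ...) {
  cat(sprintf("atom_types: %d atoms, %d ULS-labeled, %d distinct types\n",
              length(x$types), length(x$uls_atoms),
              length(unique(x$types))))
  invisible(x)
}

#' Assign base atom types
#'
#' Non-metal atoms receive heuristic labels built from the lower-cased
#' element symbol and the bonded-neighbor count (e.g. a three-coordinate
#' carbon becomes `c3`, a four-coordinate one `c4`), so atoms in different
#' coordination environments get different lookup keys. Metal atoms carry
#' their element symbol as the type. A user-supplied per-atom label list
#' (for example produced by an external typing tool) overrides the
#' heuristic verbatim.
#'
#' @param geom A [geometry()].
#' @param topology A complete `"topology"`.
#' @param overrides Optional character vector of length N with explicit
#'   type labels (at most 4 characters each).
#' @return An `"atom_types"` assignment (ULS labels not yet applied).
#' @export
assign_base_types <- function(geom, topology, overrides = NULL) {
  stopifnot(inherits(geom, "geometry"), inherits(topology, "topology"))
  n <- geom$n_atoms
  metals <- topology$metal_indices
  if (!is.null(overrides)) {
    overrides <- as.character(overrides)
    if (length(overrides) != n)
      stopf("type override list has %d entries for %d atoms",
            length(overrides), n)
    if (any(nchar(overrides) > 4L))
      stop("type labels are limited to 4 characters", call. = FALSE)
    types <- overrides
  } else {
    degree <- vapply(seq_len(n), function(i)
      length(neighbors_of(topology, i)), integer(1L))
    types <- paste0(tolower(geom$elements), degree)
    types[metals] <- geom$elements[metals]
  }
  provenance <- rep("base", n)
  provenance[metals] <- "metal"
  new_atom_types(types, provenance)
}

# suffix alphabet for the k-th metal: digits for the first, upper-case
# letters for the second, lower-case for the third, digit+letter pairs
# afterwards; every stream is disjoint from every other
.uls_suffix_stream <- function(k) {
  if (k == 1L) as.character(1:99)
  else if (k == 2L) c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))
  else if (k == 3L) c(letters, as.vector(t(outer(letters, letters, paste0))))
  else paste0(LETTERS, k - 3L) # letter+digit pairs for the 4th metal on
}

#' Apply the unique labeling strategy (ULS)
#'
#' Every atom that coordinates a metal receives its own atom type: the
#' coordinating atoms of the first metal are labeled element+digit
#' (`N1`, `N2`, ...), those of the second metal element+letter
#' (`OA`, `OB`, ...), and subsequent metals continue through further
#' deterministic alphabets. Labels are globally unique; a collision with an
#' existing label advances the alphabet. An atom bridging two metals keeps
#' the label given by its first metal.
#'
#' @param assignment An `"atom_types"` from [assign_base_types()].
#' @param topology A `"topology"` with coordination spheres populated.
#' @return The completed `"atom_types"` with `uls_atoms` set.
#' @export
apply_uls <- function(assignment, topology) {
  stopifnot(inherits(assignment, "atom_types"),
            inherits(topology, "topology"))
  metals <- topology$metal_indices
  if (!length(metals))
    stop("ULS needs at least one metal with a coordination sphere",
         call. = FALSE)
  types <- assignment$types
  provenance <- assignment$provenance
  used <- unique(types)
  uls_atoms <- integer(0)
  for (k in seq_along(metals)) {
    m <- metals[k]
    coord <- topology$coordination[[as.character(m)]]
    if (is.null(coord))
      stopf("no coordination sphere recorded for metal atom %d", m)
    if (length(coord) > 99L)
      stopf("metal atom %d has %d coordinating atoms; the label alphabet supports at most 99",
            m, length(coord))
    stream <- .uls_suffix_stream(k)
    pos <- 1L
    for (a in coord) {
      if (a %in% uls_atoms) next # bridging atom already labeled
      if (provenance[a] == "metal") next # metal-metal bond: keep element type
      el <- .uls_element_of(types, a, provenance)
      repeat {
        if (pos > length(stream))
          stopf("ULS label alphabet exhausted for metal %d", m)
        lab <- paste0(el, stream[pos])
        pos <- pos + 1L
        if (nchar(lab) > 4L)
          stopf("ULS label '%s' exceeds 4 characters", lab)
        if (!(lab %in% used)) break
      }
      types[a] <- lab
      provenance[a] <- "uls"
      used <- c(used, lab)
      uls_atoms <- c(uls_atoms, a)
    }
  }
  new_atom_types(types, provenance, uls_atoms)
}

# the element stem for a ULS label comes from the atom's element, recovered
# from the heuristic/base label via the stored geometry-free information:
# base labels are lower-cased element + digits, metals the element itself.
# The stem keeps the conventional capitalization (N, O, Cl ...).
.uls_element_of <- function(types, a, provenance) {
  stem <- sub("[0-9]+$", "", types[a])
  if (provenance[a] == "base")
    stem <- paste0(toupper(substr(stem, 1L, 1L)),
                   substring(stem, 2L))
  substr(stem, 1L, 2L)
}

#' Canonical parameter key for a bonded term
#'
#' Maps a bond, angle or dihedral (as atom indices) to the canonical,
#' reverse-symmetric tuple of its atom-type labels, joined with `-`.
#' `key(A,B,C)` equals `key(C,B,A)`; with ULS labels in place, chemically
#' distinct metal terms never share a key.
#'
#' @param term Integer vector of 2 (bond), 3 (angle) or 4 (dihedral) atom
#'   indices.
#' @param assignment An `"atom_types"`.
#' @return A single character key, e.g. `"N1-Ru-N2"`.
#' @export
parameter_key <- function(term, assignment) {
  stopifnot(inherits(assignment, "atom_types"))
  labels <- assignment$types[term]
  canonical_type_key(labels)
}

canonical_type_key <- function(labels) {
  n <- length(labels)
  if (!(n %in% c(2L, 3L, 4L)))
    stop("term must have 2, 3 or 4 atoms", call. = FALSE)
  rev_labels <- rev(labels)
  for (i in seq_len(n)) {
    if (labels[i] < rev_labels[i]) break
    if (labels[i] > rev_labels[i]) { labels <- rev_labels; break }
  }
  paste(labels, collapse = "-")
}
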