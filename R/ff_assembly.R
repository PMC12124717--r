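# Hybrid parameter assembly: transferable-database lookups for the organic
# scaffold, Seminario values for every metal-involving term (and as fallback
# for organic terms the database misses), UFF-derived metal Lennard-Jones
# entries, and zero-barrier dihedrals at the metal center.

#' Load a transferable parameter database
#'
#' Parses an Amber frcmod-style parameter file (sections MASS, BOND, ANGLE,
#' DIHE, IMPROPER, NONBON; a title line is allowed before the first section)
#' into canonical-key lookup tables. Called with `path = NULL` it returns
#' the small embedded database of common GAFF-like organic types, so the
#' package is usable without any external file.
#'
#' @param path Path to a frcmod/parameter file, or `NULL` for the embedded
#'   fallback database.
#' @return An object of class `"ff_database"` with named lists `bonds`,
#'   `angles`, `dihedrals`, `nonbon`, `mass`.
#' @examples
#' db <- load_parameter_database(
#'   system.file("extdata", "gaff_subset.frcmod", package = "metalff"))
#' database_lookup(db, c("ca", "ca"), "bond")
#' @export
load_parameter_database <- function(path = NULL) {
  if (is.null(path)) return(default_parameter_database())
  if (!file.exists(path)) stopf("parameter database not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  db <- list(bonds = list(), angles = list(), dihedrals = list(),
             nonbon = list(), mass = list())
  section <- NA_character_
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    line <- trimws(raw)
    if (!nzchar(line)) next
    up <- toupper(line)
    if (grepl("^(MASS|BOND|ANGL|DIHE|IMPROPER|IMPR|NONB)", up)) {
      key <- substr(up, 1L, 4L)
      section <- switch(key, MASS = "mass", BOND = "bonds",
                        ANGL = "angles", DIHE = "dihedrals",
                        IMPR = "impropers", NONB = "nonbon")
      next
    }
    if (is.na(section)) next # title line
    parsed <- tryCatch(
      .parse_frcmod_record(line, section),
      error = function(e) stopf("parameter file line %d: %s", ln,
                                conditionMessage(e)))
    if (is.null(parsed)) next
    if (section == "bonds") {
      db$bonds[[canonical_type_key(parsed$types)]] <-
        list(k = parsed$values[1L], r_eq = parsed$values[2L])
    } else if (section == "angles") {
      db$angles[[canonical_type_key(parsed$types)]] <-
        list(k = parsed$values[1L], theta_eq = parsed$values[2L])
    } else if (section == "dihedrals") {
      key <- canonical_type_key(parsed$types)
      term <- list(idivf = parsed$values[1L], pk = parsed$values[2L],
                   phase = parsed$values[3L], pn = abs(parsed$values[4L]))
      db$dihedrals[[key]] <- c(db$dihedrals[[key]], list(term))
    } else if (section == "nonbon") {
      db$nonbon[[parsed$types[1L]]] <-
        list(rmin_half = parsed$values[1L], eps = parsed$values[2L])
    } else if (section == "mass") {
      db$mass[[parsed$types[1L]]] <- parsed$values[1L]
    }
  }
  structure(db, class = "ff_database")
}

# splits a frcmod record into the dash-separated type field and trailing
# numbers; the type field ends where the first numeric token starts
.parse_frcmod_record <- function(line, section) {
  toks <- strsplit(line, "\\s+")[[1L]]
  is_num <- grepl("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?$", toks)
  first_num <- which(is_num)[1L]
  if (is.na(first_num))
    stop("no numeric fields found in record '", line, "'")
  type_field <- paste(toks[seq_len(first_num - 1L)], collapse = "")
  types <- strsplit(type_field, "-", fixed = TRUE)[[1L]]
  values <- suppressWarnings(as.numeric(toks[is_num]))
  n_types <- switch(section, mass = 1L, nonbon = 1L, bonds = 2L,
                    angles = 3L, dihedrals = 4L, impropers = 4L)
  if (section %in% c("mass", "nonbon")) {
    if (first_num != 2L)
      stop("malformed ", section, " record '", line, "'")
    types <- toks[1L]
  } else if (length(types) != n_types) {
    stop("expected ", n_types, " dash-separated types in '", line, "'")
  }
  if (section == "impropers") return(NULL) # recorded but unused
  list(types = types, values = values)
}

#' Embedded fallback database of common organic types
#'
#' A small GAFF-like table (aromatic/aliphatic carbon, amine/aromatic
#' nitrogen, carbonyl/hydroxyl oxygen, common hydrogens and halogens) keyed
#' both by classic GAFF names and by the package's heuristic
#' element+coordination labels, so test molecules resolve without any
#' external download.
#'
#' @return An `"ff_database"`.
#' @export
default_parameter_database <- function() {
  db <- list(bonds = list(), angles = list(), dihedrals = list(),
             nonbon = list(), mass = list())
  add_bond <- function(a, b, k, r)
    db$bonds[[canonical_type_key(c(a, b))]] <<- list(k = k, r_eq = r)
  add_angle <- function(a, b, c, k, th)
    db$angles[[canonical_type_key(c(a, b, c))]] <<-
      list(k = k, theta_eq = th)
  add_lj <- function(t, r2, e)
    db$nonbon[[t]] <<- list(rmin_half = r2, eps = e)
  # classic GAFF names
  add_bond("ca", "ca", 478.40, 1.387)
  add_bond("ca", "ha", 344.30, 1.087)
  add_bond("c3", "c3", 303.10, 1.535)
  add_bond("c3", "hc", 337.30, 1.092)
  add_angle("ca", "ca", "ca", 67.18, 119.97)
  add_angle("ca", "ca", "ha", 48.46, 120.01)
  add_angle("hc", "c3", "hc", 39.43, 108.35)
  # heuristic element+coordination labels used by assign_base_types
  add_bond("c4", "h1", 337.30, 1.092)
  add_bond("c4", "c4", 303.10, 1.535)
  add_angle("h1", "c4", "h1", 39.43, 108.35)
  add_lj("ca", 1.9080, 0.0860)
  add_lj("c3", 1.9080, 0.1094)
  add_lj("ha", 1.4590, 0.0150)
  add_lj("hc", 1.4870, 0.0157)
  structure(db, class = "ff_database")
}

#' @export
print.ff_database <- function(x, ...) {
  cat(sprintf(
    "ff_database: %d bonds, %d angles, %d dihedrals, %d LJ, %d masses\n",
    length(x$bonds), length(x$angles), length(x$dihedrals),
    length(x$nonbon), length(x$mass)))
  invisible(x)
}

#' Look up a database entry by canonical type key
#'
#' @param database An `"ff_database"`.
#' @param types Character vector of 2 (bond), 3 (angle) or 4 (dihedral)
#'   type labels; direction is canonicalized.
#' @param what `"bond"`, `"angle"` or `"dihedral"`.
#' @return The stored entry, or `NULL` on a miss (a miss is a signal, not
#'   an error).
#' @export
database_lookup <- function(database, types,
                            what = c("bond", "angle", "dihedral")) {
  what <- match.arg(what)
  key <- canonical_type_key(types)
  switch(what, bond = database$bonds[[key]],
         angle = database$angles[[key]],
         dihedral = database$dihedrals[[key]])
}

#' UFF-derived metal Lennard-Jones entry
#'
#' Retrieves the UFF nonbonded parameters of a metal element and applies the
#' scaling convention used for Amber compatibility: the vdW distance is
#' halved (yielding R_min/2 directly), while the well depth is kept
#' unchanged.
#'
#' @param element Metal element symbol.
#' @return A list of class `"lj_entry"`: `type`, `rmin_half` (Å), `eps`
#'   (kcal/mol), `source`.
#' @export
metal_lj <- function(element) {
  if (!(element %in% rownames(.uff_metal_lj)))
    stopf("element '%s' is not in the embedded UFF metal table; supply the Lennard-Jones entry manually",
          element)
  structure(list(type = element,
                 rmin_half = .uff_metal_lj[element, "x"] / 2,
                 eps = .uff_metal_lj[element, "d"],
                 source = "uff"),
            class = "lj_entry")
}

#' Assemble the complete force-field parameter set
#'
#' Merge rule, per term: a bond/angle that involves a metal atom always
#' takes its Seminario value; otherwise a database hit wins; a database miss
#' falls back to the Seminario value and is flagged missing. Dihedrals
#' involving a metal are written as single zero-barrier terms; organic
#' dihedrals come from the database or, when absent, are zeroed and
#' flagged. Lennard-Jones terms: UFF (halved R) for metal types, database
#' or element-level fallback for the rest. Masses come from the embedded
#' atomic-weight table (database MASS entries win when present). Every
#' entry carries a provenance tag in {seminario, database, uff, zeroed}.
#'
#' @param topology A complete `"topology"`.
#' @param assignment An `"atom_types"`.
#' @param seminario_params Output of [all_metal_parameters()].
#' @param database An `"ff_database"` (default: embedded fallback).
#' @param charges Optional [charge_set()] stored on the result.
#' @param geom The [geometry()] (for element lookups).
#' @return An object of class `"ff_parameter_set"` with named lists
#'   `bonds`, `angles`, `dihedrals`, `lj`, `masses`, plus `charges`,
#'   `provenance` counts and the `missing` key log.
#' @export
assemble_parameters <- function(topology, assignment, seminario_params,
                                geom, database = NULL, charges = NULL) {
  stopifnot(inherits(topology, "topology"), inherits(assignment, "atom_types"))
  database <- database %||% default_parameter_database()
  metals <- topology$metal_indices
  types <- assignment$types
  if (any(nchar(types) > 4L))
    stop("type labels are limited to 4 characters", call. = FALSE)
  missing_keys <- character(0)

  bonds <- list()
  for (k in seq_len(nrow(topology$bonds))) {
    term <- topology$bonds[k, ]
    key <- parameter_key(term, assignment)
    if (!is.null(bonds[[key]])) next # symmetric duplicate collapses
    sem <- seminario_params$bonds[[k]]
    if (sem$involves_metal) {
      bonds[[key]] <- list(k = sem$k_out, r_eq = sem$r_eq,
                           provenance = "seminario")
    } else {
      hit <- database_lookup(database, types[term], "bond")
      if (!is.null(hit)) {
        bonds[[key]] <- list(k = hit$k, r_eq = hit$r_eq,
                             provenance = "database")
      } else {
        missing_keys <- c(missing_keys, paste0("bond ", key))
        bonds[[key]] <- list(k = sem$k_out, r_eq = sem$r_eq,
                             provenance = "seminario")
      }
    }
  }

  angles <- list()
  for (k in seq_len(nrow(topology$angles))) {
    term <- topology$angles[k, ]
    key <- parameter_key(term, assignment)
    if (!is.null(angles[[key]])) next
    sem <- seminario_params$angles[[k]]
    if (sem$involves_metal) {
      angles[[key]] <- list(k = sem$k_theta_out, theta_eq = sem$theta_eq,
                            provenance = "seminario",
                            degenerate = isTRUE(sem$degenerate))
    } else {
      hit <- database_lookup(database, types[term], "angle")
      if (!is.null(hit)) {
        angles[[key]] <- list(k = hit$k, theta_eq = hit$theta_eq,
                              provenance = "database", degenerate = FALSE)
      } else {
        missing_keys <- c(missing_keys, paste0("angle ", key))
        angles[[key]] <- list(k = sem$k_theta_out, theta_eq = sem$theta_eq,
                              provenance = "seminario",
                              degenerate = isTRUE(sem$degenerate))
      }
    }
  }

  zero_term <- list(list(idivf = 1, pk = 0, phase = 0, pn = 1))
  dihedrals <- list()
  for (k in seq_len(nrow(topology$dihedrals))) {
    term <- topology$dihedrals[k, ]
    key <- parameter_key(term, assignment)
    if (!is.null(dihedrals[[key]])) next
    if (any(term %in% metals)) {
      dihedrals[[key]] <- list(terms = zero_term, provenance = "zeroed")
    } else {
      hit <- database_lookup(database, types[term], "dihedral")
      if (!is.null(hit)) {
        dihedrals[[key]] <- list(terms = hit, provenance = "database")
      } else {
        missing_keys <- c(missing_keys, paste0("dihedral ", key))
        dihedrals[[key]] <- list(terms = zero_term, provenance = "zeroed")
      }
    }
  }

  lj <- list()
  masses <- list()
  for (i in seq_len(topology$n_atoms)) {
    ty <- types[i]
    if (!is.null(lj[[ty]])) next
    el <- geom$elements[i]
    masses[[ty]] <- database$mass[[ty]] %||% element_mass(el)
    if (i %in% metals || (assignment$provenance[i] == "metal")) {
      e <- metal_lj(el)
      lj[[ty]] <- list(rmin_half = e$rmin_half, eps = e$eps,
                       provenance = "uff")
    } else {
      hit <- database$nonbon[[ty]]
      if (!is.null(hit)) {
        lj[[ty]] <- list(rmin_half = hit$rmin_half, eps = hit$eps,
                         provenance = "database")
      } else if (el %in% rownames(.organic_lj_fallback)) {
        lj[[ty]] <- list(rmin_half = .organic_lj_fallback[el, "rmin_half"],
                         eps = .organic_lj_fallback[el, "eps"],
                         provenance = "database")
      } else {
        stopf("no Lennard-Jones parameters resolvable for type '%s' (element %s)",
              ty, el)
      }
    }
  }

  prov_count <- function(entries)
    table(vapply(entries, `[[`, character(1L), "provenance"))
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 lj = lj, masses = masses, charges = charges,
                 types = types,
                 metal_types = unique(types[metals]),
                 missing = missing_keys,
                 provenance = list(bonds = prov_count(bonds),
                                   angles = prov_count(angles),
                                   dihedrals = prov_count(dihedrals),
                                   lj = prov_count(lj))),
            class = "ff_parameter_set")
}

#' @export
print.ff_parameter_set <- function(x, ...) {
  cat(sprintf(
    "ff_parameter_set: %d bond, %d angle, %d dihedral keys; %d LJ types\n",
    length(x$bonds), length(x$angles), length(x$dihedrals), length(x$lj)))
  for (nm in c("bonds", "angles", "dihedrals")) {
    pv <- x$provenance[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                paste(names(pv), as.integer(pv), sep = ":", collapse = " ")))
  }
  if (length(x$missing))
    cat("  flagged missing in database:", length(x$missing), "\n")
  invisible(x)
}
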