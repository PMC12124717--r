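# End-to-end parametrization pipeline: the programmatic surface behind the
# command-line front end (inst/scripts/metalff.R). Mirrors the workflow
# read -> perceive -> type (ULS) -> Seminario -> assemble -> write.

#' Parametrize a metal complex end to end
#'
#' Reads the optimized geometry, Cartesian Hessian and (optionally) atomic
#' charges; perceives connectivity; assigns base types and unique metal
#' labels; computes Seminario force constants for the whole molecule;
#' merges with the transferable database; attaches UFF metal
#' Lennard-Jones terms; and writes `<residue>.frcmod`, `<residue>.mol2`
#' and `<residue>.pdb` (plus `<residue>.lib` on request) into `out_dir`.
#' Nothing is written until every step has succeeded.
#'
#' @param xyz Path to the XYZ geometry.
#' @param hessian Path to the Hessian file.
#' @param hessian_dialect `"plain"`, `"gaussian_fchk"` or `"orca_hess"`.
#' @param charges Optional path to a two-column or mol2 charge file.
#' @param charges_dialect Dialect for `charges`.
#' @param database Optional path to an Amber frcmod/parameter database;
#'   the embedded fallback database is used when absent.
#' @param out_dir Output directory (created if needed).
#' @param uls Apply the unique labeling strategy (default TRUE; turning it
#'   off collapses all symmetric metal terms onto shared keys and exists
#'   for demonstration only).
#' @param tolerance_factor Bond-perception tolerance.
#' @param residue Residue name for the output files.
#' @param total_charge Total molecular charge in e.
#' @param type_overrides Optional path to a one-label-per-line type file.
#' @param emit_lib Also write the minimal leap library file.
#' @return Invisibly, a list with the output `files`, the assembled
#'   `params`, the `assignment`, `topology` and a provenance `log`.
#' @export
parametrize <- function(xyz, hessian,
                        hessian_dialect = c("plain", "gaussian_fchk",
                                            "orca_hess"),
                        charges = NULL, charges_dialect = "two_column",
                        database = NULL, out_dir = ".",
                        uls = TRUE, tolerance_factor = 1.25,
                        residue = "LIG", total_charge = 0L,
                        type_overrides = NULL, emit_lib = FALSE) {
  hessian_dialect <- match.arg(hessian_dialect)
  geom <- read_xyz(xyz, total_charge = total_charge)
  hess <- read_hessian(hessian, dialect = hessian_dialect,
                       n_atoms = geom$n_atoms)
  qset <- if (!is.null(charges))
    read_charges(charges, dialect = charges_dialect, geom = geom)
  top <- build_topology(geom, tolerance_factor = tolerance_factor)
  overrides <- if (!is.null(type_overrides)) {
    ov <- trimws(readLines(type_overrides, warn = FALSE))
    ov[nzchar(ov)]
  }
  assignment <- assign_base_types(geom, top, overrides = overrides)
  if (uls) assignment <- apply_uls(assignment, top)
  sem <- all_metal_parameters(hess, geom, top)
  db <- if (is.null(database)) default_parameter_database() else
    load_parameter_database(database)
  params <- assemble_parameters(top, assignment, sem, geom,
                                database = db, charges = qset)
  n_terms <- nrow(top$bonds) + nrow(top$angles) + nrow(top$dihedrals)
  log <- list(
    n_atoms = geom$n_atoms,
    n_terms = n_terms,
    n_keys = length(params$bonds) + length(params$angles) +
      length(params$dihedrals),
    provenance = params$provenance,
    missing = params$missing)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(frcmod = file.path(out_dir, paste0(residue, ".frcmod")),
             mol2 = file.path(out_dir, paste0(residue, ".mol2")),
             pdb = file.path(out_dir, paste0(residue, ".pdb")))
  write_frcmod(params, files[["frcmod"]])
  write_mol2(geom, top, assignment, qset, residue = residue,
             path = files[["mol2"]])
  write_pdb(geom, residue = residue, path = files[["pdb"]])
  if (emit_lib) {
    files <- c(files, lib = file.path(out_dir, paste0(residue, ".lib")))
    write_lib(geom, top, assignment, qset, residue = residue,
              path = files[["lib"]])
  }
  invisible(list(files = files, params = params, assignment = assignment,
                 topology = top, geometry = geom, log = log))
}

#' Constrained charge derivation over an ESP grid
#'
#' Reads the geometry, ESP grid and constraint file, builds chemical
#' equivalence classes, runs the constrained restrained-ESP fit, and
#' rewrites the mol2 file with the updated charges.
#'
#' @param xyz Path to the XYZ geometry.
#' @param grid Path to the ESP grid file (`x y z V` lines).
#' @param constraints Path to the constraint file (`atom_index charge`
#'   lines plus a `total <Q>` line); `NULL` runs a plain restrained fit.
#' @param total_charge Total charge when no constraint file is given.
#' @param out_dir Output directory.
#' @param residue Residue name.
#' @param two_stage Use the two-stage restrained fit.
#' @param use_equivalence Constrain chemically equivalent atoms to share a
#'   charge (default TRUE).
#' @param tolerance_factor Bond-perception tolerance.
#' @return Invisibly, a list with the fitted `charges`, the `classes` and
#'   the output `files`.
#' @export
derive_charges <- function(xyz, grid, constraints = NULL,
                           total_charge = 0L, out_dir = ".",
                           residue = "LIG", two_stage = FALSE,
                           use_equivalence = TRUE,
                           tolerance_factor = 1.25) {
  geom <- read_xyz(xyz, total_charge = total_charge)
  g <- read_esp_grid(grid)
  cons <- if (!is.null(constraints))
    read_constraints(constraints, n_atoms = geom$n_atoms)
  top <- build_topology(geom, tolerance_factor = tolerance_factor,
                        require_metal = FALSE)
  cls <- if (use_equivalence) equivalence_classes(top, geom) else NULL
  tq <- if (!is.null(cons)) cons$total_charge else total_charge
  geom$total_charge <- as.integer(tq)
  spec <- restraint_spec(total_charge = tq,
                         fixed = if (!is.null(cons)) cons$fixed,
                         classes = cls)
  fit <- fit_charges(geom, g, spec, two_stage = two_stage)
  assignment <- assign_base_types(geom, top)
  if (length(top$metal_indices)) assignment <- apply_uls(assignment, top)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(mol2 = file.path(out_dir, paste0(residue, ".mol2")),
             charges = file.path(out_dir, paste0(residue, ".resp.chg")))
  write_mol2(geom, top, assignment, fit, residue = residue,
             path = files[["mol2"]])
  writeLines(sprintf("%-3s %12.6f", geom$elements, fit$charges),
             files[["charges"]])
  invisible(list(charges = fit, classes = cls, files = files,
                 geometry = geom, topology = top))
}
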