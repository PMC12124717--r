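# Restrained electrostatic-potential (RESP-style) charge fitting with exact
# linear equality constraints: total charge, per-atom fixed charges and
# chemical-equivalence classes, plus the standard hyperbolic restraint
# handled by iterative reweighting.

#' ESP grid container
#'
#' @param points M×3 matrix of grid-point coordinates in Å.
#' @param potentials Length-M electrostatic potentials in atomic units.
#' @param source Free-text provenance note.
#' @return An object of class `"esp_grid"`.
#' @export
esp_grid <- function(points, potentials, source = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  potentials <- as.numeric(potentials)
  if (ncol(points) != 3L || nrow(points) != length(potentials))
    stop("grid needs an M x 3 point matrix and M potentials", call. = FALSE)
  structure(list(points = points, potentials = potentials,
                 n_points = nrow(points), source = as.character(source)[1L]),
            class = "esp_grid")
}

#' Read and write plain-text ESP grids
#'
#' Format: one `x y z V` record per line, coordinates in Å, potential in
#' atomic units. Comment lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param grid An [esp_grid()] (for the writer).
#' @return `read_esp_grid()` returns an [esp_grid()]; `write_esp_grid()`
#'   its text, invisibly.
#' @export
read_esp_grid <- function(path) {
  if (!file.exists(path)) stopf("ESP grid file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  vals <- lapply(strsplit(trimws(lines), "\\s+"), function(tk) {
    v <- suppressWarnings(as.numeric(tk))
    if (length(v) != 4L || anyNA(v))
      stop("ESP grid lines must be 'x y z V'", call. = FALSE)
    v
  })
  m <- do.call(rbind, vals)
  esp_grid(m[, 1:3, drop = FALSE], m[, 4L], source = path)
}

#' @rdname read_esp_grid
#' @export
write_esp_grid <- function(grid, path) {
  stopifnot(inherits(grid, "esp_grid"))
  lines <- c("# esp grid: x y z (angstrom)  V (a.u.)",
             sprintf("%18.10f %18.10f %18.10f %20.12E",
                     grid$points[, 1L], grid$points[, 2L],
                     grid$points[, 3L], grid$potentials))
  writeLines(lines, path)
  invisible(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Chemical-equivalence classes by neighborhood refinement
#'
#' Partitions the atoms by iterated color refinement: the initial color is
#' the element symbol (or the atom-type label when `use_types = TRUE`, which
#' forces ULS-labeled coordinating atoms into singleton classes); each round
#' appends the sorted multiset of neighbor colors, until a fixed point.
#' Atoms in the same class are constrained to share a charge during
#' fitting.
#'
#' @param topology A `"topology"` with bonds populated.
#' @param geom The [geometry()].
#' @param assignment Optional `"atom_types"`; required for
#'   `use_types = TRUE`.
#' @param use_types Start from type labels instead of elements.
#' @return A list of integer index vectors (a partition of `1:N`), ordered
#'   by smallest member.
#' @export
equivalence_classes <- function(topology, geom, assignment = NULL,
                                use_types = FALSE) {
  stopifnot(inherits(topology, "topology"))
  n <- topology$n_atoms
  colors <- if (use_types) {
    if (is.null(assignment))
      stop("use_types = TRUE needs an atom-type assignment", call. = FALSE)
    assignment$types
  } else geom$elements
  nb <- lapply(seq_len(n), function(i) neighbors_of(topology, i))
  repeat {
    sig <- vapply(seq_len(n), function(i)
      paste(colors[i], paste(sort(colors[nb[[i]]]), collapse = ","),
            sep = "|"), character(1L))
    new_colors <- as.character(match(sig, unique(sig)))
    if (length(unique(new_colors)) == length(unique(colors))) break
    colors <- new_colors
  }
  cls <- split(seq_len(n), colors)
  cls <- cls[order(vapply(cls, min, integer(1L)))]
  names(cls) <- NULL
  cls
}

#' Restraint specification for charge fitting
#'
#' @param total_charge Integer total molecular charge in e.
#' @param fixed Named numeric vector: names are atom indices, values the
#'   charges those atoms are pinned to.
#' @param classes Optional equivalence partition from
#'   [equivalence_classes()]; members of a class share one charge.
#' @param strength Hyperbolic restraint strength in atomic units
#'   (default 0.0005); 0 disables the restraint.
#' @param tightness Hyperbolic width parameter b (default 0.1 e).
#' @param restrain_hydrogens Restrain hydrogen atoms too (default FALSE,
#'   the usual RESP convention).
#' @return An object of class `"restraint_spec"`.
#' @export
restraint_spec <- function(total_charge, fixed = NULL, classes = NULL,
                           strength = 0.0005, tightness = 0.1,
                           restrain_hydrogens = FALSE) {
  if (!is_count(total_charge))
    stop("total_charge must be an integer", call. = FALSE)
  if (!is.null(fixed)) {
    idx <- suppressWarnings(as.integer(names(fixed)))
    if (anyNA(idx))
      stop("fixed charges must be named by atom index", call. = FALSE)
  }
  if (strength < 0) stop("restraint strength must be >= 0", call. = FALSE)
  structure(list(total_charge = as.integer(total_charge),
                 fixed = fixed, classes = classes,
                 strength = strength, tightness = tightness,
                 restrain_hydrogens = isTRUE(restrain_hydrogens)),
            class = "restraint_spec")
}

#' Constrained restrained-ESP charge fit
#'
#' Minimizes the sum of squared deviations between the grid potentials and
#' the point-charge Coulomb potential, plus the hyperbolic restraint
#' `a * (sqrt(q^2 + b^2) - b)` on non-hydrogen, non-fixed atoms, subject to
#' exact linear equality constraints: total charge, fixed per-atom charges
#' and intra-class charge equality. The restraint is handled by iterative
#' reweighting (KKT solve per iteration) until the largest charge update
#' falls below `tol`; fixed charges are honored exactly and the residual
#' total-charge defect (solver roundoff) is redistributed uniformly over
#' the free atoms so conservation is exact.
#'
#' A two-stage variant refits only the atoms in multi-member equivalence
#' classes in a second pass with a stronger restraint (0.001 a.u.) while
#' freezing all other atoms at their first-stage values.
#'
#' @param geom A [geometry()].
#' @param grid An [esp_grid()].
#' @param spec A [restraint_spec()].
#' @param two_stage Run the two-stage variant.
#' @param maxit Maximum reweighting iterations (default 200).
#' @param tol Convergence threshold on max |Δq| in e (default 1e-6).
#' @return A [charge_set()] with `method_tag = "resp"`.
#' @export
fit_charges <- function(geom, grid, spec, two_stage = FALSE,
                        maxit = 200L, tol = 1e-6) {
  stopifnot(inherits(geom, "geometry"), inherits(grid, "esp_grid"),
            inherits(spec, "restraint_spec"))
  n <- geom$n_atoms
  if (grid$n_points < n)
    stopf("ESP grid has %d points for %d atoms; need at least N",
          grid$n_points, n)
  fixed <- .normalize_fixed(spec, n)
  q <- .resp_solve(geom, grid, spec, fixed, maxit, tol)
  if (two_stage) {
    refit <- sort(unlist(Filter(function(cl) length(cl) > 1L,
                                spec$classes %||% list())))
    refit <- setdiff(refit, as.integer(names(fixed)))
    if (length(refit)) {
      frozen <- setdiff(seq_len(n), refit)
      fixed2 <- stats::setNames(q[frozen], frozen)
      fixed2 <- c(fixed, fixed2[!(names(fixed2) %in% names(fixed))])
      spec2 <- spec
      spec2$strength <- 0.001
      spec2$fixed <- fixed2
      q <- .resp_solve(geom, grid, spec2, .normalize_fixed(spec2, n),
                       maxit, tol)
    }
  }
  charge_set(q, method_tag = "resp")
}

# resolves fixed charges, propagating a fix across its whole equivalence
# class; conflicting fixes inside a class are infeasible
.normalize_fixed <- function(spec, n) {
  fixed <- spec$fixed
  if (is.null(fixed)) fixed <- stats::setNames(numeric(0), character(0))
  idx <- as.integer(names(fixed))
  if (any(idx < 1L | idx > n))
    stopf("fixed-charge atom index out of range 1..%d", n)
  if (anyDuplicated(idx)) {
    vals <- split(as.numeric(fixed), idx)
    if (any(vapply(vals, function(v) max(v) - min(v) > 1e-12, logical(1L))))
      stop("conflicting fixed charges for the same atom", call. = FALSE)
    fixed <- stats::setNames(vapply(vals, `[`, numeric(1L), 1L), names(vals))
    idx <- as.integer(names(fixed))
  }
  for (cl in spec$classes %||% list()) {
    hit <- intersect(cl, idx)
    if (!length(hit)) next
    v <- unique(round(fixed[as.character(hit)], 12L))
    if (length(v) > 1L)
      stop("equivalence class members carry conflicting fixed charges",
           call. = FALSE)
    add <- setdiff(cl, idx)
    if (length(add)) {
      fixed <- c(fixed, stats::setNames(rep(v, length(add)), add))
      idx <- as.integer(names(fixed))
    }
  }
  fixed[order(as.integer(names(fixed)))]
}

.resp_solve <- function(geom, grid, spec, fixed, maxit, tol) {
  n <- geom$n_atoms
  # design matrix in atomic units: distances in Bohr
  d <- matrix(0, grid$n_points, n)
  for (i in seq_len(n)) {
    dv <- sweep(grid$points, 2L, geom$coordinates[i, ])
    d[, i] <- sqrt(rowSums(dv^2)) / .bohr_to_angstrom
  }
  if (any(d * .bohr_to_angstrom < 0.1))
    stop("ESP grid point within 0.1 Å of an atom", call. = FALSE)
  a_mat <- 1 / d
  bmat <- crossprod(a_mat)
  bvec <- as.numeric(crossprod(a_mat, grid$potentials))

  cons <- list(list(row = rep(1, n), rhs = spec$total_charge))
  fixed_idx <- as.integer(names(fixed))
  for (j in seq_along(fixed)) {
    row <- numeric(n); row[fixed_idx[j]] <- 1
    cons[[length(cons) + 1L]] <- list(row = row, rhs = as.numeric(fixed[j]))
  }
  for (cl in spec$classes %||% list()) {
    cl <- sort(cl)
    if (length(cl) < 2L) next
    if (all(cl %in% fixed_idx)) next # already pinned
    for (j in cl[-1L]) {
      row <- numeric(n); row[cl[1L]] <- 1; row[j] <- -1
      cons[[length(cons) + 1L]] <- list(row = row, rhs = 0)
    }
  }
  cmat <- do.call(rbind, lapply(cons, `[[`, "row"))
  rhs <- vapply(cons, `[[`, numeric(1L), "rhs")

  restrained <- rep(TRUE, n)
  if (!spec$restrain_hydrogens) restrained[geom$elements == "H"] <- FALSE
  restrained[fixed_idx] <- FALSE

  q <- numeric(n)
  converged <- FALSE
  last_delta <- NA_real_
  for (it in seq_len(maxit)) {
    rw <- numeric(n)
    if (spec$strength > 0)
      rw[restrained] <- spec$strength /
        sqrt(q[restrained]^2 + spec$tightness^2)
    kkt <- rbind(cbind(bmat + diag(rw, n), t(cmat)),
                 cbind(cmat, matrix(0, nrow(cmat), nrow(cmat))))
    sol <- tryCatch(solve(kkt, c(bvec, rhs)),
                    error = function(e)
                      stop("constraint system is singular or infeasible: ",
                           conditionMessage(e), call. = FALSE))
    q_new <- sol[seq_len(n)]
    last_delta <- max(abs(q_new - q))
    q <- q_new
    if (last_delta < tol || spec$strength == 0) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("restrained fit did not converge in %d iterations (last max |dq| = %.3g e)",
          maxit, last_delta)
  # snap constraints exactly: fixed atoms at targets, then distribute the
  # residual total-charge defect over the free atoms (uniformly, which
  # preserves intra-class equality for fully free classes)
  q[fixed_idx] <- as.numeric(fixed)
  free <- setdiff(seq_len(n), fixed_idx)
  if (length(free))
    q[free] <- q[free] + (spec$total_charge - sum(q)) / length(free)
  q
}

#' Read a charge-constraint file
#'
#' Plain text: lines `atom_index charge` plus one `total <Q>` line; `#`
#' comments allowed.
#'
#' @param path File path.
#' @param n_atoms Atom count for index validation.
#' @return A list with `fixed` (named numeric) and `total_charge`.
#' @export
read_constraints <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) stopf("constraint file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fixed <- numeric(0)
  total <- NULL
  for (ln in lines) {
    tk <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tolower(tk[1L]) == "total") {
      total <- as.numeric(tk[2L])
    } else {
      i <- suppressWarnings(as.integer(tk[1L]))
      v <- suppressWarnings(as.numeric(tk[2L]))
      if (is.na(i) || is.na(v))
        stopf("malformed constraint line: '%s'", ln)
      if (!is.null(n_atoms) && (i < 1L || i > n_atoms))
        stopf("constraint atom index %d out of range 1..%d", i, n_atoms)
      fixed[as.character(i)] <- v
    }
  }
  if (is.null(total))
    stop("constraint file must contain a 'total <Q>' line", call. = FALSE)
  list(fixed = fixed, total_charge = total)
}
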