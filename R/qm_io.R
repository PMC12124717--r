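# Readers and writers for the quantum-chemistry input files: XYZ geometries,
# Cartesian Hessians in three dialects, and atomic charge lists.

#' Molecular geometry container
#'
#' Holds element symbols and Cartesian coordinates in Å, plus the total
#' molecular charge and a free-text title. All file readers and the
#' parametrization pipeline operate on this object.
#'
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric N×3 matrix of coordinates in Å.
#' @param total_charge Integer total charge in e.
#' @param title Free-text comment.
#' @return An object of class `"geometry"`: a list with fields `elements`,
#'   `coordinates`, `total_charge`, `title`, `n_atoms`.
#' @examples
#' geometry(c("O", "H", "H"),
#'          rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399, 0.9266, 0)))
#' @export
geometry <- function(elements, coordinates, total_charge = 0L, title = "") {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (length(elements) < 1L)
    stop("geometry needs at least one atom", call. = FALSE)
  if (ncol(coordinates) != 3L || nrow(coordinates) != length(elements))
    stopf("coordinate matrix must be %d x 3, got %d x %d",
          length(elements), nrow(coordinates), ncol(coordinates))
  element_number(elements) # validates symbols
  if (!is_count(total_charge))
    stop("total_charge must be an integer", call. = FALSE)
  structure(list(elements = as.character(elements),
                 coordinates = coordinates,
                 total_charge = as.integer(total_charge),
                 title = as.character(title)[1L],
                 n_atoms = length(elements)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms, total charge %+d\n", x$n_atoms,
              x$total_charge))
  cat("  composition:", paste(names(table(x$elements)),
                              table(x$elements), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write XYZ geometry files
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `El x y z` record per atom (coordinates in Å). Atom order is preserved.
#'
#' @param path File path.
#' @param total_charge Total molecular charge to attach (not stored in XYZ).
#' @param geom A [geometry()] object (for `write_xyz`).
#' @param digits Decimal places written per coordinate.
#' @return `read_xyz()` returns a [geometry()]; `write_xyz()` returns the
#'   file text invisibly.
#' @export
read_xyz <- function(path, total_charge = 0L) {
  if (!file.exists(path)) stopf("XYZ file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ file too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ line 1 must be a positive integer atom count", call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stopf("XYZ header declares %d atoms but body has %d coordinate lines",
          n, length(body))
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  elements <- character(n)
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 4L)
      stopf("XYZ body line %d is malformed: '%s'", i + 2L, body[i])
    elements[i] <- tk[1L]
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(v))
      stopf("XYZ body line %d has non-numeric coordinates", i + 2L)
    xyz[i, ] <- v
  }
  geometry(elements, xyz, total_charge = total_charge,
           title = trimws(lines[2L]))
}

#' @rdname read_xyz
#' @export
write_xyz <- function(geom, path = NULL, digits = 8L) {
  stopifnot(inherits(geom, "geometry"))
  fmt <- sprintf("%%-3s %%16.%df %%16.%df %%16.%df", digits, digits, digits)
  lines <- c(as.character(geom$n_atoms),
             geom$title,
             vapply(seq_len(geom$n_atoms), function(i) {
               sprintf(fmt, geom$elements[i], geom$coordinates[i, 1L],
                       geom$coordinates[i, 2L], geom$coordinates[i, 3L])
             }, character(1L)))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(lines, path)
  invisible(text)
}

#' Cartesian Hessian container
#'
#' A 3N×3N matrix of energy second derivatives in Hartree/Bohr². The
#' constructor symmetrizes the matrix; an asymmetry larger than `1e-6`
#' triggers a warning (QM printing noise is smaller than that).
#'
#' @param matrix 3N×3N numeric matrix, Hartree/Bohr².
#' @param n_atoms Atom count N.
#' @param source_dialect One of `"gaussian_fchk"`, `"orca_hess"`, `"plain"`.
#' @return An object of class `"cartesian_hessian"`.
#' @export
cartesian_hessian <- function(matrix, n_atoms,
                              source_dialect = c("plain", "gaussian_fchk",
                                                 "orca_hess")) {
  source_dialect <- match.arg(source_dialect)
  matrix <- as.matrix(matrix)
  if (!is_count(n_atoms) || n_atoms < 1L)
    stop("n_atoms must be a positive integer", call. = FALSE)
  side <- 3L * as.integer(n_atoms)
  if (nrow(matrix) != side || ncol(matrix) != side)
    stopf("Hessian must be %d x %d for %d atoms, got %d x %d",
          side, side, n_atoms, nrow(matrix), ncol(matrix))
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-6)
    warning(sprintf(
      "Hessian asymmetry %.3g exceeds 1e-6; symmetrizing (H + t(H))/2", asym),
      call. = FALSE)
  matrix <- (matrix + t(matrix)) / 2
  structure(list(matrix = matrix, n_atoms = as.integer(n_atoms),
                 source_dialect = source_dialect),
            class = "cartesian_hessian")
}

#' @export
print.cartesian_hessian <- function(x, ...) {
  cat(sprintf("cartesian_hessian: %d atoms (%d x %d), dialect %s\n",
              x$n_atoms, 3L * x$n_atoms, 3L * x$n_atoms, x$source_dialect))
  invisible(x)
}

#' Read a Cartesian Hessian
#'
#' Supports three dialects: the `Cartesian Force Constants` block of a
#' Gaussian formatted checkpoint (lower triangle, row-major, five values per
#' line), the `$hessian` section of an ORCA `.hess` file (dimension line,
#' then column-blocked values), and a plain dense-matrix text format with an
#' explicit unit header (written by [write_hessian()]). All dialects are
#' returned in Hartree/Bohr² and symmetrized.
#'
#' @param path File path.
#' @param dialect One of `"gaussian_fchk"`, `"orca_hess"`, `"plain"`.
#' @param n_atoms Expected atom count from the companion geometry; checked
#'   against the file when given.
#' @return A [cartesian_hessian()].
#' @export
read_hessian <- function(path, dialect = c("plain", "gaussian_fchk",
                                           "orca_hess"), n_atoms = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("Hessian file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  h <- switch(dialect,
              plain = .read_hessian_plain(lines),
              gaussian_fchk = .read_hessian_fchk(lines),
              orca_hess = .read_hessian_orca(lines))
  n <- nrow(h) %/% 3L
  if (!is.null(n_atoms) && n != n_atoms)
    stopf("Hessian encodes %d atoms but the geometry has %d", n, n_atoms)
  cartesian_hessian(h, n, source_dialect = dialect)
}

.read_hessian_plain <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  head_idx <- grep("^\\s*natoms\\s+\\d+", lines)
  if (!length(head_idx))
    stop("plain Hessian: expected a 'natoms <N>' header line", call. = FALSE)
  n <- as.integer(sub("^\\s*natoms\\s+(\\d+).*", "\\1", lines[head_idx[1L]]))
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[-seq_len(head_idx[1L])]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  side <- 3L * n
  if (length(vals) != side * side)
    stopf("plain Hessian: expected %d values, found %d", side * side,
          length(vals))
  matrix(vals, side, side, byrow = TRUE)
}

.read_hessian_fchk <- function(lines) {
  marker <- grep("^Cartesian Force Constants", lines)
  if (!length(marker))
    stop("fchk Hessian: 'Cartesian Force Constants' section not found",
         call. = FALSE)
  header <- lines[marker[1L]]
  len <- as.integer(sub(".*N=\\s*(\\d+).*", "\\1", header))
  vals <- numeric(0)
  i <- marker[1L] + 1L
  while (length(vals) < len && i <= length(lines)) {
    tk <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (anyNA(tk)) break
    vals <- c(vals, tk)
    i <- i + 1L
  }
  if (length(vals) < len)
    stopf("fchk Hessian: section declares %d values, found %d", len,
          length(vals))
  vals <- vals[seq_len(len)]
  # len = s(s+1)/2 for side s
  side <- as.integer((sqrt(8 * len + 1) - 1) / 2)
  if (side * (side + 1L) / 2L != len || side %% 3L != 0L)
    stopf("fchk Hessian: triangle length %d is not 3N(3N+1)/2", len)
  h <- matrix(0, side, side)
  k <- 1L
  for (i in seq_len(side)) for (j in seq_len(i)) {
    h[i, j] <- vals[k]
    h[j, i] <- vals[k]
    k <- k + 1L
  }
  h
}

.read_hessian_orca <- function(lines) {
  marker <- grep("^\\s*\\$hessian\\s*$", lines)
  if (!length(marker))
    stop("ORCA Hessian: '$hessian' section not found", call. = FALSE)
  i <- marker[1L] + 1L
  side <- suppressWarnings(as.integer(trimws(lines[i])))
  if (is.na(side) || side < 3L)
    stop("ORCA Hessian: dimension line after $hessian is malformed",
         call. = FALSE)
  h <- matrix(NA_real_, side, side)
  i <- i + 1L
  while (anyNA(h) && i <= length(lines)) {
    if (grepl("^\\s*\\$", lines[i])) break
    cols <- suppressWarnings(as.integer(strsplit(trimws(lines[i]),
                                                 "\\s+")[[1L]]))
    if (anyNA(cols)) stopf("ORCA Hessian: bad column header at line %d", i)
    cols <- cols + 1L # 0-based in file
    for (r in seq_len(side)) {
      i <- i + 1L
      tk <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      row <- as.integer(tk[1L]) + 1L
      vals <- as.numeric(tk[-1L])
      if (row != r || length(vals) != length(cols))
        stopf("ORCA Hessian: malformed row at line %d", i)
      h[row, cols] <- vals
    }
    i <- i + 1L
  }
  if (anyNA(h))
    stop("ORCA Hessian: $hessian block ended before the matrix was complete",
         call. = FALSE)
  h
}

#' Write a Cartesian Hessian in any supported dialect
#'
#' Emits the same layouts [read_hessian()] parses, so synthetic Hessians can
#' exercise every reader. The plain dialect carries a unit header; the fchk
#' dialect writes the lower triangle five values per line; the ORCA dialect
#' writes 0-based column blocks of five.
#'
#' @param hessian A [cartesian_hessian()].
#' @param path Output path.
#' @param dialect Target dialect.
#' @return The file text, invisibly.
#' @export
write_hessian <- function(hessian, path,
                          dialect = c("plain", "gaussian_fchk",
                                      "orca_hess")) {
  stopifnot(inherits(hessian, "cartesian_hessian"))
  dialect <- match.arg(dialect)
  h <- hessian$matrix
  side <- nrow(h)
  lines <- switch(dialect,
    plain = {
      rows <- apply(h, 1L, function(r)
        paste(sprintf("%22.14E", r), collapse = " "))
      c("# cartesian hessian, units hartree/bohr^2",
        sprintf("natoms %d", hessian$n_atoms), rows)
    },
    gaussian_fchk = {
      # fchk wants the row-major lower triangle, i.e. the column-major
      # upper triangle of the transpose
      tri <- t(h)[upper.tri(h, diag = TRUE)]
      grp <- split(tri, ceiling(seq_along(tri) / 5))
      c(sprintf("Number of atoms                            I %16d",
                hessian$n_atoms),
        sprintf("Cartesian Force Constants                  R   N= %11d",
                length(tri)),
        vapply(grp, function(g) paste(sprintf("%16.8E", g), collapse = ""),
               character(1L)))
    },
    orca_hess = {
      out <- c("$hessian", sprintf("%d", side))
      for (start in seq(1L, side, by = 5L)) {
        cols <- start:min(start + 4L, side)
        out <- c(out, paste(sprintf("%10d", cols - 1L), collapse = ""))
        for (r in seq_len(side)) {
          out <- c(out, paste0(sprintf("%6d", r - 1L),
                               paste(sprintf("%14.10f", h[r, cols]),
                                     collapse = " ")))
        }
      }
      c(out, "$end")
    })
  writeLines(lines, path)
  invisible(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Atomic partial charge container
#'
#' @param charges Numeric per-atom charges in e, geometry atom order.
#' @param method_tag Free-text provenance tag (e.g. `"esp"`, `"chelpg"`,
#'   `"resp"`).
#' @param total_charge Optional known total charge; when given, the sum of
#'   charges must agree within `1e-4` e.
#' @return An object of class `"charge_set"`.
#' @export
charge_set <- function(charges, method_tag = "esp", total_charge = NULL) {
  charges <- as.numeric(charges)
  if (anyNA(charges)) stop("charges contain NA", call. = FALSE)
  if (!is.null(total_charge) &&
      abs(sum(charges) - total_charge) > 1e-4)
    stopf("charges sum to %.6f but total charge is %+d", sum(charges),
          total_charge)
  structure(list(charges = charges, method_tag = as.character(method_tag)[1L]),
            class = "charge_set")
}

#' Read atomic charges
#'
#' Two dialects: `two_column` (one `element charge` pair per line, geometry
#' atom order) and `mol2` (the charge column of TRIPOS ATOM records).
#'
#' @param path File path.
#' @param dialect `"two_column"` or `"mol2"`.
#' @param geom Optional [geometry()]; charge count and (for two_column)
#'   element symbols are validated against it.
#' @param method_tag Provenance tag stored on the result.
#' @return A [charge_set()].
#' @export
read_charges <- function(path, dialect = c("two_column", "mol2"),
                         geom = NULL, method_tag = "esp") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("charge file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "two_column") {
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "\\s+")
    q <- vapply(seq_along(toks), function(i) {
      tk <- toks[[i]]
      if (length(tk) < 2L)
        stopf("charge file line %d is malformed", i)
      v <- suppressWarnings(as.numeric(tk[2L]))
      if (is.na(v)) stopf("non-numeric charge on line %d: '%s'", i, tk[2L])
      v
    }, numeric(1L))
    els <- vapply(toks, `[`, character(1L), 1L)
  } else {
    atom_start <- grep("^@<TRIPOS>ATOM", lines)
    if (!length(atom_start))
      stop("mol2: @<TRIPOS>ATOM section not found", call. = FALSE)
    i <- atom_start[1L] + 1L
    q <- numeric(0)
    els <- character(0)
    while (i <= length(lines) && !grepl("^@<TRIPOS>", lines[i])) {
      tk <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(tk) >= 9L) {
        v <- suppressWarnings(as.numeric(tk[9L]))
        if (is.na(v)) stopf("mol2: non-numeric charge on line %d", i)
        q <- c(q, v)
        els <- c(els, sub("\\..*$", "", tk[6L]))
      }
      i <- i + 1L
    }
  }
  if (!is.null(geom)) {
    if (length(q) != geom$n_atoms)
      stopf("charge file has %d entries but the geometry has %d atoms",
            length(q), geom$n_atoms)
  }
  charge_set(q, method_tag = method_tag,
             total_charge = if (!is.null(geom)) geom$total_charge else NULL)
}
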