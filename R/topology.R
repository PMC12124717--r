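# Bond perception from interatomic distances, angle/dihedral enumeration,
# metal identification and linked-metal-group validation.

new_topology <- function(n_atoms, bonds = matrix(integer(0), 0L, 2L),
                         angles = matrix(integer(0), 0L, 3L),
                         dihedrals = matrix(integer(0), 0L, 4L),
                         metal_indices = integer(0),
                         coordination = list()) {
  structure(list(n_atoms = as.integer(n_atoms), bonds = bonds,
                 angles = angles, dihedrals = dihedrals,
                 metal_indices = metal_indices, coordination = coordination),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(
    "topology: %d atoms, %d bonds, %d angles, %d dihedrals, %d metal(s)\n",
    x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
    length(x$metal_indices)))
  invisible(x)
}

neighbors_of <- function(topology, i) {
  b <- topology$bonds
  sort(c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L]))
}

#' Perceive bonds from interatomic distances
#'
#' Atoms i and j are bonded iff their distance is at most
#' `tolerance_factor * (r_cov(i) + r_cov(j))`, with covalent radii from the
#' embedded element table. Pairs closer than 0.4 Å are rejected as
#' overlapping atoms. Increasing the tolerance factor can only add bonds.
#'
#' @param geom A [geometry()].
#' @param tolerance_factor Positive multiplier on the covalent-radius sum
#'   (default 1.25).
#' @return A `"topology"` object with only the bond list populated; bonds
#'   are stored smaller-index-first and sorted.
#' @export
perceive_bonds <- function(geom, tolerance_factor = 1.25) {
  stopifnot(inherits(geom, "geometry"))
  if (!is.numeric(tolerance_factor) || tolerance_factor <= 0)
    stop("tolerance_factor must be positive", call. = FALSE)
  n <- geom$n_atoms
  rc <- covalent_radius(geom$elements)
  d <- as.matrix(stats::dist(geom$coordinates))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dist_ij <- d[pairs]
  if (any(dist_ij < 0.4)) {
    k <- which.min(dist_ij)
    stopf("atoms %d and %d overlap (distance %.3f Å < 0.4 Å)",
          pairs[k, 1L], pairs[k, 2L], dist_ij[k])
  }
  thr <- tolerance_factor * (rc[pairs[, 1L]] + rc[pairs[, 2L]])
  keep <- dist_ij <= thr
  bonds <- pairs[keep, , drop = FALSE]
  bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
  dimnames(bonds) <- NULL
  new_topology(n, bonds = bonds)
}

#' Enumerate angles and dihedrals from the bond graph
#'
#' Angles are all unordered neighbor pairs about each vertex B, stored as
#' (A, B, C) with A < C. Dihedrals are all simple paths A–B–C–D over
#' distinct atoms, stored with the lexicographically smaller orientation
#' first. Every term expands only from perceived bonds.
#'
#' @param topology A `"topology"` with bonds populated.
#' @return The topology with `angles` and `dihedrals` filled in.
#' @export
enumerate_angles_dihedrals <- function(topology) {
  stopifnot(inherits(topology, "topology"))
  nb <- lapply(seq_len(topology$n_atoms), function(i)
    neighbors_of(topology, i))
  ang <- list()
  for (b in seq_len(topology$n_atoms)) {
    v <- nb[[b]]
    if (length(v) >= 2L) {
      cmb <- utils::combn(v, 2L)
      ang[[length(ang) + 1L]] <- cbind(cmb[1L, ], b, cmb[2L, ])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    matrix(integer(0), 0L, 3L)
  if (nrow(angles))
    angles <- angles[order(angles[, 2L], angles[, 1L], angles[, 3L]), ,
                     drop = FALSE]
  dih <- list()
  bonds <- topology$bonds
  for (k in seq_len(nrow(bonds))) {
    bb <- bonds[k, 1L]; cc <- bonds[k, 2L]
    for (a in setdiff(nb[[bb]], cc)) for (d in setdiff(nb[[cc]], bb)) {
      if (a == d) next
      quad <- c(a, bb, cc, d)
      if (quad[4L] < quad[1L] ||
          (quad[4L] == quad[1L] && quad[3L] < quad[2L]))
        quad <- rev(quad)
      dih[[length(dih) + 1L]] <- quad
    }
  }
  dihedrals <- if (length(dih)) unique(do.call(rbind, dih)) else
    matrix(integer(0), 0L, 4L)
  if (nrow(dihedrals))
    dihedrals <- dihedrals[order(dihedrals[, 1L], dihedrals[, 2L],
                                 dihedrals[, 3L], dihedrals[, 4L]), ,
                           drop = FALSE]
  dimnames(angles) <- NULL
  dimnames(dihedrals) <- NULL
  topology$angles <- angles
  topology$dihedrals <- dihedrals
  topology
}

#' Identify metal centers and their coordination spheres
#'
#' Metals are recognized from the embedded metal-element set (alkali,
#' alkaline-earth, transition and post-transition metals, lanthanides,
#' actinides). The coordination sphere of a metal is its sorted bonded
#' neighbor list. At least one metal center is expected.
#'
#' @param geom A [geometry()].
#' @param topology A `"topology"` with bonds populated.
#' @return The topology with `metal_indices` and `coordination` filled in.
#' @export
find_metals_and_spheres <- function(geom, topology) {
  stopifnot(inherits(geom, "geometry"), inherits(topology, "topology"))
  metals <- which(is_metal_element(geom$elements))
  if (!length(metals))
    stop("no metal center found: at least one metal atom is expected",
         call. = FALSE)
  topology$metal_indices <- metals
  topology$coordination <- stats::setNames(
    lapply(metals, function(m) neighbors_of(topology, m)),
    as.character(metals))
  topology
}

#' Group linked metals and enforce the multimetal limit
#'
#' Two metals are linked if they are bonded to each other or share a
#' bridging coordinating atom. Returns the connected components of that
#' linkage graph; any component with more than four metals is rejected.
#'
#' @param topology A `"topology"` with metal fields populated.
#' @param max_linked Maximum metals per linked group (default 4).
#' @return A list of integer vectors, one per metal cluster.
#' @export
linked_metal_groups <- function(topology, max_linked = 4L) {
  stopifnot(inherits(topology, "topology"))
  metals <- topology$metal_indices
  if (!length(metals))
    stop("metal_indices not populated", call. = FALSE)
  nm <- length(metals)
  adj <- matrix(FALSE, nm, nm)
  nb <- lapply(metals, function(m) neighbors_of(topology, m))
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (i >= j) next
    linked <- metals[j] %in% nb[[i]] ||
      length(intersect(nb[[i]], nb[[j]])) > 0L
    adj[i, j] <- adj[j, i] <- linked
  }
  seen <- rep(FALSE, nm)
  groups <- list()
  for (s in seq_len(nm)) {
    if (seen[s]) next
    comp <- s
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      nxt <- which(adj[cur, ] & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      queue <- c(queue, nxt)
    }
    groups[[length(groups) + 1L]] <- sort(metals[comp])
  }
  sizes <- lengths(groups)
  if (any(sizes > max_linked)) {
    bad <- groups[[which(sizes > max_linked)[1L]]]
    stopf("linked metal group of size %d exceeds the maximum of %d (atoms: %s)",
          max(sizes), max_linked, paste(bad, collapse = ", "))
  }
  groups
}

#' One-call topology construction
#'
#' Convenience wrapper: perceive bonds, enumerate angles/dihedrals, locate
#' metals and validate the linked-metal limit.
#'
#' @inheritParams perceive_bonds
#' @param require_metal When `TRUE` (default) a metal center must be present.
#' @return A complete `"topology"`.
#' @export
build_topology <- function(geom, tolerance_factor = 1.25,
                           require_metal = TRUE) {
  top <- perceive_bonds(geom, tolerance_factor)
  top <- enumerate_angles_dihedrals(top)
  if (require_metal || any(is_metal_element(geom$elements))) {
    top <- find_metals_and_spheres(geom, top)
    linked_metal_groups(top)
  }
  top
}
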