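# Synthetic-data generators: idealized complex geometries, analytic
# spring-network Hessians (the exact oracle for the Seminario formulas),
# randomized planar star networks, and Coulomb ESP grids from known
# charges. Everything is deterministic under a fixed seed.

#' Idealized metal-complex geometries
#'
#' Exact textbook coordination geometries with the metal at the origin:
#' `octahedral` (6 ligands, 90°/180° angles), `square_planar` (4 ligands in
#' the xy plane), `linear` (2 trans ligands), `bimetallic` (a direct
#' metal-metal bond; 3 oxygens on the first metal and 5 on the second) and
#' `tris_bidentate` (an octahedron whose 6 coordinating atoms are joined
#' pairwise into three cis chelates). The chelate link of `tris_bidentate`
#' is carried by the returned topology as a direct donor-donor edge (the
#' idealized model has no carbon backbone), so use the returned topology
#' rather than re-perceiving from distances.
#'
#' @param kind Complex shape (see above).
#' @param metal Metal element (defaults depend on `kind`).
#' @param ligand Donor-atom element.
#' @param bond_length Metal-donor distance in Å.
#' @return A list with `geometry` and complete `topology`.
#' @export
make_ideal_complex <- function(kind = c("octahedral", "square_planar",
                                        "linear", "bimetallic",
                                        "tris_bidentate"),
                               metal = NULL, ligand = NULL,
                               bond_length = NULL) {
  kind <- match.arg(kind)
  oct_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  build <- function(elements, coords, extra_bonds = NULL) {
    g <- geometry(elements, coords, total_charge = 0L,
                  title = paste("ideal", kind, "complex"))
    top <- perceive_bonds(g)
    if (!is.null(extra_bonds)) {
      bonds <- rbind(top$bonds, extra_bonds)
      bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
      top$bonds <- unique(bonds)
    }
    top <- enumerate_angles_dihedrals(top)
    top <- find_metals_and_spheres(g, top)
    linked_metal_groups(top)
    list(geometry = g, topology = top)
  }
  switch(kind,
    octahedral = {
      metal <- metal %||% "Ru"; ligand <- ligand %||% "N"
      d <- bond_length %||% 2.10
      build(c(metal, rep(ligand, 6L)),
            rbind(c(0, 0, 0), oct_dirs * d))
    },
    square_planar = {
      metal <- metal %||% "Pt"; ligand <- ligand %||% "N"
      d <- bond_length %||% 2.00
      build(c(metal, rep(ligand, 4L)),
            rbind(c(0, 0, 0), oct_dirs[1:4, ] * d))
    },
    linear = {
      metal <- metal %||% "Hg"; ligand <- ligand %||% "Cl"
      d <- bond_length %||% 2.30
      build(c(metal, rep(ligand, 2L)),
            rbind(c(0, 0, 0), c(d, 0, 0), c(-d, 0, 0)))
    },
    bimetallic = {
      metal <- metal %||% "Rh"; ligand <- ligand %||% "O"
      d <- bond_length %||% 2.05
      mm <- 2.45
      m2 <- c(mm, 0, 0)
      coords <- rbind(
        c(0, 0, 0), m2,
        c(-d, 0, 0), c(0, d, 0), c(0, -d, 0),            # 3 O on metal 1
        m2 + c(d, 0, 0), m2 + c(0, d, 0), m2 + c(0, -d, 0),
        m2 + c(0, 0, d), m2 + c(0, 0, -d))               # 5 O on metal 2
      build(c(metal, metal, rep(ligand, 8L)), coords)
    },
    tris_bidentate = {
      metal <- metal %||% "Ru"; ligand <- ligand %||% "N"
      d <- bond_length %||% 2.10
      # three cis chelate pairs: (+x,+y), (-x,+z), (-y,-z)
      dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0),
                    c(0, 0, 1), c(0, -1, 0), c(0, 0, -1))
      chelate <- rbind(c(2L, 3L), c(4L, 5L), c(6L, 7L))
      build(c(metal, rep(ligand, 6L)),
            rbind(c(0, 0, 0), dirs * d), extra_bonds = chelate)
    })
}

#' Analytic spring-network model
#'
#' A harmonic network over the given bonds: each bond carries a stretching
#' constant `k_bond` along the bond axis and perpendicular stiffnesses that
#' are either isotropic (`k_perp`) or split into an in-plane and an
#' out-of-plane component relative to a reference `normal` (`k_perp` along
#' `normal x u`, `k_perp2` along `normal`). All constants are in
#' Hartree/Bohr². The anisotropic form makes the perpendicular eigenpairs
#' of each interaction block unique and aligned with the angle plane of a
#' planar network, which is what the closed-form angle oracle
#' `1/k = sum 1/(R² k_perp)` requires.
#'
#' @param geom A [geometry()].
#' @param topology A `"topology"` with bonds populated.
#' @param k_bond Per-bond stretching constants (recycled).
#' @param k_perp Per-bond perpendicular constants (recycled).
#' @param k_perp2 Optional second perpendicular constant; needs `normal`.
#' @param normal Reference plane normal (length-3), for the anisotropic
#'   form.
#' @return A list of class `"spring_model"`.
#' @export
spring_model <- function(geom, topology, k_bond, k_perp,
                         k_perp2 = NULL, normal = NULL) {
  stopifnot(inherits(geom, "geometry"), inherits(topology, "topology"))
  nb <- nrow(topology$bonds)
  k_bond <- rep_len(k_bond, nb)
  k_perp <- rep_len(k_perp, nb)
  if (!is.null(k_perp2)) {
    if (is.null(normal))
      stop("anisotropic perpendicular stiffness needs a reference normal",
           call. = FALSE)
    k_perp2 <- rep_len(k_perp2, nb)
    normal <- unit_vector(normal)
  }
  structure(list(geometry = geom, topology = topology, k_bond = k_bond,
                 k_perp = k_perp, k_perp2 = k_perp2, normal = normal),
            class = "spring_model")
}

#' Assemble the analytic Hessian of a spring network
#'
#' Builds the exact second-derivative matrix of
#' `E = sum ½ k_bond (Δd·u)² + sum ½ |P Δd|²_k` at the reference geometry:
#' for each bond the 3×3 stiffness block is
#' `K = k_bond u uᵀ + k_ip p pᵀ + k_op n nᵀ` (or `k_perp (I − u uᵀ)` in the
#' isotropic case), accumulated with the usual `+K/−K` pattern, so the
#' interaction block of a bonded pair is exactly `−K` and the matrix is
#' symmetric and translation-invariant by construction.
#'
#' @param model A [spring_model()].
#' @return A [cartesian_hessian()].
#' @export
make_spring_hessian <- function(model) {
  stopifnot(inherits(model, "spring_model"))
  geom <- model$geometry
  top <- model$topology
  n <- geom$n_atoms
  h <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(nrow(top$bonds))) {
    a <- top$bonds[k, 1L]; b <- top$bonds[k, 2L]
    u <- unit_vector(geom$coordinates[a, ] - geom$coordinates[b, ])
    kb <- model$k_bond[k]
    if (is.null(model$k_perp2)) {
      kmat <- kb * tcrossprod(u) + model$k_perp[k] * (diag(3) - tcrossprod(u))
    } else {
      nrm <- model$normal
      p <- unit_vector(cross3(nrm, u))
      nn <- cross3(u, p) # in-plane-orthogonal completion of the triad
      kmat <- kb * tcrossprod(u) + model$k_perp[k] * tcrossprod(p) +
        model$k_perp2[k] * tcrossprod(nn)
    }
    ia <- (3L * (a - 1L) + 1L):(3L * a)
    ib <- (3L * (b - 1L) + 1L):(3L * b)
    h[ia, ia] <- h[ia, ia] + kmat
    h[ib, ib] <- h[ib, ib] + kmat
    h[ia, ib] <- h[ia, ib] - kmat
    h[ib, ia] <- h[ib, ia] - kmat
  }
  cartesian_hessian(h, n, source_dialect = "plain")
}

#' Randomized planar star network
#'
#' A metal at the origin with `n_ligands` donor atoms at random angles in
#' the xy plane (minimum angular separation 12°) and random bond lengths,
#' with random anisotropic spring constants per bond. These networks are
#' the randomized test bed for the Seminario oracles: every bond constant
#' and every closed-form angle constant is known exactly.
#'
#' @param n_ligands Number of donor atoms (2-6).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param metal,ligand Element symbols.
#' @return A list with `geometry`, `topology`, `model` (a
#'   [spring_model()]) and `hessian`.
#' @export
random_planar_star <- function(n_ligands, seed, metal = "Ru",
                               ligand = "N") {
  stopifnot(n_ligands >= 2L, n_ligands <= 6L)
  set.seed(seed)
  repeat {
    ang <- sort(stats::runif(n_ligands, 0, 2 * pi))
    gaps <- diff(c(ang, ang[1L] + 2 * pi))
    if (min(gaps) > 12 * pi / 180) break
  }
  r <- stats::runif(n_ligands, 1.9, 2.3)
  coords <- rbind(c(0, 0, 0), cbind(r * cos(ang), r * sin(ang), 0))
  g <- geometry(c(metal, rep(ligand, n_ligands)), coords,
                title = "random planar star")
  bonds <- cbind(1L, 2L:(n_ligands + 1L))
  top <- new_topology(n_ligands + 1L, bonds = bonds)
  top <- enumerate_angles_dihedrals(top)
  top <- find_metals_and_spheres(g, top)
  model <- spring_model(g, top,
                        k_bond = stats::runif(n_ligands, 0.1, 0.5),
                        k_perp = stats::runif(n_ligands, 0.02, 0.08),
                        k_perp2 = stats::runif(n_ligands, 0.55, 0.9),
                        normal = c(0, 0, 1))
  list(geometry = g, topology = top, model = model,
       hessian = make_spring_hessian(model))
}

#' Synthetic ESP grid from known charges
#'
#' Samples `n_points` grid points on shells at 1.4-2.0 times an effective
#' atomic radius (covalent radius + 0.9 Å) around randomly chosen atoms,
#' rejecting points that fall inside the shell of any other atom, and
#' evaluates the exact Coulomb potential of `true_charges` at each point
#' (atomic units, distances in Bohr). Used as the inverse-problem oracle
#' for the charge fitter.
#'
#' @param geom A [geometry()].
#' @param true_charges Length-N generating charges in e.
#' @param n_points Number of grid points (at least 4N).
#' @param seed Integer seed.
#' @return An [esp_grid()].
#' @export
make_esp_grid <- function(geom, true_charges, n_points, seed) {
  stopifnot(inherits(geom, "geometry"))
  n <- geom$n_atoms
  if (length(true_charges) != n)
    stopf("true_charges has %d entries for %d atoms", length(true_charges), n)
  if (n_points < 4L * n)
    stopf("n_points must be at least 4 x N = %d", 4L * n)
  set.seed(seed)
  shell <- covalent_radius(geom$elements) + 0.9
  pts <- matrix(NA_real_, n_points, 3L)
  got <- 0L
  tries <- 0L
  while (got < n_points) {
    tries <- tries + 1L
    if (tries > 200L * n_points)
      stop("ESP grid sampling failed to place points", call. = FALSE)
    a <- ((tries - 1L) %% n) + 1L
    v <- stats::rnorm(3L)
    u <- v / sqrt(sum(v^2))
    p <- geom$coordinates[a, ] + stats::runif(1L, 1.4, 2.0) * shell[a] * u
    dmin <- sqrt(rowSums(sweep(geom$coordinates, 2L, p)^2))
    if (any(dmin < 1.3 * shell)) next
    got <- got + 1L
    pts[got, ] <- p
  }
  pot <- numeric(n_points)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(pts, 2L, geom$coordinates[i, ])^2)) /
      .bohr_to_angstrom
    pot <- pot + true_charges[i] / di
  }
  esp_grid(pts, pot, source = sprintf("synthetic coulomb grid (seed %d)",
                                      seed))
}
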