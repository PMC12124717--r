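# Seminario-method force constants: harmonic bond and angle stiffnesses from
# eigendecompositions of 3x3 interatomic sub-blocks of the Cartesian Hessian.
#
# Conventions implemented exactly as stated with the method:
#   bond:  k_AB = sum_i (v_i . u_AB)^2 lambda_i        (squared projections)
#   angle: 1/k_theta = 1/(R_AB^2 S_AB) + 1/(R_CB^2 S_CB),
#          S_XB = sum_i lambda_i |u_P . v_i|           (absolute projections)
# Raw constants are in Hartree/Bohr^2 (angles: Hartree/rad^2 after the
# R^2 weighting with R in Bohr); outputs are converted to kcal/mol/A^2 and
# kcal/(mol rad^2) respectively and doubled for the Amber K(r-r0)^2 form.
# The projection asymmetry between the two formulas (squared vs absolute) is
# deliberate: both are applied as printed with the method.

.bond_unit_factor <- function() 2 * .hartree_to_kcal / .bohr_to_angstrom^2
.angle_unit_factor <- function() 2 * .hartree_to_kcal

#' Interatomic sub-Hessian
#'
#' Extracts the 3×3 interaction block coupling atoms A and B from the full
#' Cartesian Hessian, sign-flipped and symmetrized:
#' `block = -(H_AB + t(H_BA)) / 2`. The eigendecomposition (ascending
#' eigenvalues, orthonormal eigenvectors) is attached.
#'
#' @param hessian A [cartesian_hessian()].
#' @param A,B Distinct 1-based atom indices.
#' @return A list of class `"sub_hessian"` with `block`, `values`
#'   (ascending) and `vectors` (columns aligned with `values`).
#' @export
interaction_subhessian <- function(hessian, A, B) {
  stopifnot(inherits(hessian, "cartesian_hessian"))
  n <- hessian$n_atoms
  if (!is_count(A) || !is_count(B) || A < 1L || B < 1L || A > n || B > n)
    stopf("atom indices must lie in 1..%d", n)
  if (A == B) stop("sub-Hessian requires two distinct atoms", call. = FALSE)
  ia <- (3L * (A - 1L) + 1L):(3L * A)
  ib <- (3L * (B - 1L) + 1L):(3L * B)
  h_ab <- hessian$matrix[ia, ib, drop = FALSE]
  h_ba <- hessian$matrix[ib, ia, drop = FALSE]
  block <- -(h_ab + t(h_ba)) / 2
  eig <- eigen(block, symmetric = TRUE)
  ord <- order(eig$values)
  structure(list(block = block, values = eig$values[ord],
                 vectors = eig$vectors[, ord, drop = FALSE],
                 atoms = c(A, B)),
            class = "sub_hessian")
}

#' Bond force constant from the Hessian
#'
#' Projects the sub-Hessian eigenpairs of the atom pair onto the bond unit
#' vector: `k_raw = sum_i (v_i . u_AB)^2 lambda_i` in Hartree/Bohr². The
#' output constant is converted to kcal/mol/Å² and doubled for the Amber
#' harmonic form `K (r - r_eq)^2`; the equilibrium length is the distance in
#' the input (optimized) geometry.
#'
#' @param hessian A [cartesian_hessian()].
#' @param geom The matching [geometry()].
#' @param A,B Bonded atom indices.
#' @return A list of class `"bond_parameter"`: `atoms`, `k_raw`
#'   (Hartree/Bohr²), `k_out` (kcal/mol/Å²), `r_eq` (Å), `stable` flag.
#' @export
bond_force_constant <- function(hessian, geom, A, B) {
  stopifnot(inherits(geom, "geometry"))
  sub <- interaction_subhessian(hessian, A, B)
  u <- unit_vector(geom$coordinates[A, ] - geom$coordinates[B, ])
  proj <- as.numeric(crossprod(sub$vectors, u))
  k_raw <- sum(proj^2 * sub$values)
  stable <- k_raw > 0
  if (!stable)
    warning(sprintf(
      "bond %d-%d: non-positive force constant %.3g (unstable mode along bond)",
      A, B, k_raw), call. = FALSE)
  structure(list(atoms = c(A, B), k_raw = k_raw,
                 k_out = .bond_unit_factor() * k_raw,
                 r_eq = vnorm(geom$coordinates[A, ] - geom$coordinates[B, ]),
                 stable = stable),
            class = "bond_parameter")
}

#' Angle force constant from the Hessian
#'
#' For the triad A–B–C (vertex B), builds the bond unit vectors, the unit
#' normal of the angle plane and the in-plane perpendiculars
#' (`u_PA = u_N x u_AB`, `u_PC = u_CB x u_N`), eigendecomposes the AB and CB
#' sub-Hessians, and combines the reciprocal stiffnesses
#' `1/k = 1/(R_AB² S_AB) + 1/(R_CB² S_CB)` with
#' `S = sum_i lambda_i |u_P . v_i|` (terms with `lambda_i <` `lambda_min`
#' are skipped). Bond lengths enter in Bohr so the raw constant is in
#' Hartree/rad²; output is kcal/(mol rad²), doubled. The equilibrium angle
#' is measured from the input geometry.
#'
#' Collinear triads have no defined angle plane. By default they raise an
#' error; with `on_linear = "fallback"` a deterministic perpendicular axis
#' replaces the plane normal and the parameter is flagged `degenerate`
#' (used for trans angles of octahedral centers).
#'
#' @param hessian A [cartesian_hessian()].
#' @param geom The matching [geometry()].
#' @param A,B,C Atom indices, B the vertex; (A,B) and (C,B) must be bonded.
#' @param lambda_min Eigenvalue threshold below which a term is skipped
#'   (Hartree/Bohr², default 1e-8).
#' @param on_linear `"error"` or `"fallback"` for collinear triads.
#' @return A list of class `"angle_parameter"`: `atoms`, `k_theta_raw`
#'   (Hartree/rad²), `k_theta_out` (kcal/(mol rad²)), `theta_eq` (degrees),
#'   `degenerate` flag and the cached unit vectors `u_AB`, `u_CB`, `u_N`,
#'   `u_PA`, `u_PC`.
#' @export
angle_force_constant <- function(hessian, geom, A, B, C,
                                 lambda_min = 1e-8,
                                 on_linear = c("error", "fallback")) {
  stopifnot(inherits(geom, "geometry"))
  on_linear <- match.arg(on_linear)
  if (length(unique(c(A, B, C))) != 3L)
    stop("angle requires three distinct atoms", call. = FALSE)
  ab <- geom$coordinates[A, ] - geom$coordinates[B, ]
  cb <- geom$coordinates[C, ] - geom$coordinates[B, ]
  u_ab <- unit_vector(ab)
  u_cb <- unit_vector(cb)
  nvec <- cross3(u_cb, u_ab)
  degenerate <- vnorm(nvec) < 1e-8
  if (degenerate) {
    if (on_linear == "error")
      stopf("atoms %d-%d-%d are collinear: angle plane undefined", A, B, C)
    u_n <- perpendicular_axis(u_ab)
  } else {
    u_n <- nvec / vnorm(nvec)
  }
  u_pa <- cross3(u_n, u_ab)
  u_pc <- cross3(u_cb, u_n)
  stiff <- function(X, u_p) {
    sub <- interaction_subhessian(hessian, X, B)
    keep <- sub$values >= lambda_min
    sum(sub$values[keep] *
          abs(as.numeric(crossprod(sub$vectors[, keep, drop = FALSE], u_p))))
  }
  s_ab <- stiff(A, u_pa)
  s_cb <- stiff(C, u_pc)
  if (s_ab <= 0 || s_cb <= 0)
    stopf("angle %d-%d-%d: no bending stiffness resolvable (all eigenvalue terms below %.1e)",
          A, B, C, lambda_min)
  r_ab <- vnorm(ab) / .bohr_to_angstrom
  r_cb <- vnorm(cb) / .bohr_to_angstrom
  inv_k <- 1 / (r_ab^2 * s_ab) + 1 / (r_cb^2 * s_cb)
  k_raw <- 1 / inv_k
  cosang <- sum(u_ab * u_cb)
  theta <- acos(max(-1, min(1, cosang))) * 180 / pi
  structure(list(atoms = c(A, B, C), k_theta_raw = k_raw,
                 k_theta_out = .angle_unit_factor() * k_raw,
                 theta_eq = theta, degenerate = degenerate,
                 u_AB = u_ab, u_CB = u_cb, u_N = u_n,
                 u_PA = u_pa, u_PC = u_pc),
            class = "angle_parameter")
}

#' Seminario parameters for the whole molecule
#'
#' Applies the Seminario method to every bond and angle of the topology and
#' tags each parameter with whether it involves a metal atom, so assembly
#' can keep only metal terms (plus database misses). Collinear angles, such
#' as the trans angles of an octahedron, use the deterministic linear
#' fallback and come back flagged `degenerate`.
#'
#' @param hessian A [cartesian_hessian()].
#' @param geom The matching [geometry()].
#' @param topology A complete `"topology"`.
#' @param lambda_min Passed to [angle_force_constant()].
#' @return A list with `bonds` and `angles` (lists of parameter objects,
#'   each with an added `involves_metal` flag), in topology order.
#' @export
all_metal_parameters <- function(hessian, geom, topology,
                                 lambda_min = 1e-8) {
  stopifnot(inherits(topology, "topology"))
  metals <- topology$metal_indices
  bonds <- lapply(seq_len(nrow(topology$bonds)), function(k) {
    ab <- topology$bonds[k, ]
    p <- bond_force_constant(hessian, geom, ab[1L], ab[2L])
    p$involves_metal <- any(ab %in% metals)
    p
  })
  angles <- lapply(seq_len(nrow(topology$angles)), function(k) {
    abc <- topology$angles[k, ]
    p <- angle_force_constant(hessian, geom, abc[1L], abc[2L], abc[3L],
                              lambda_min = lambda_min,
                              on_linear = "fallback")
    p$involves_metal <- any(abc %in% metals)
    p
  })
  list(bonds = bonds, angles = angles)
}
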