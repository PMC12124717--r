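# Sub-Hessian extraction and the bond/angle force-constant formulas,
# checked against analytic spring constructions and independent oracles.

test_that("interaction blocks are sign-flipped, symmetrized and order-independent", {
  lin <- make_ideal_complex("linear")
  m <- spring_model(lin$geometry, lin$topology, k_bond = 0.25, k_perp = 0)
  h <- make_spring_hessian(m)
  sub <- interaction_subhessian(h, 1, 2)
  # bond along x: block k * diag(1, 0, 0), eigenvalues (0, 0, k)
  expect_equal(sub$block, 0.25 * diag(c(1, 0, 0)))
  expect_equal(sub$values, c(0, 0, 0.25))
  sub_rev <- interaction_subhessian(h, 2, 1)
  expect_equal(sub_rev$values, sub$values)
  expect_error(interaction_subhessian(h, 1, 9), "1..3")
  expect_error(interaction_subhessian(h, 2, 2), "distinct")
})

test_that("sub-Hessian eigenvalues match the characteristic-polynomial oracle", {
  set.seed(31)
  for (rep in 1:20) {
    block <- random_symmetric3()
    h <- matrix(0, 6, 6)
    h[1:3, 4:6] <- -block
    h[4:6, 1:3] <- -t(block)
    h[1:3, 1:3] <- h[4:6, 4:6] <- block + diag(3) # keep it symmetric overall
    hess <- cartesian_hessian(h, 2L)
    sub <- interaction_subhessian(hess, 1, 2)
    expect_equal(sub$values, charpoly_eigenvalues(block), tolerance = 1e-10)
    # eigen relation and orthonormality
    for (i in 1:3)
      expect_lt(max(abs(sub$block %*% sub$vectors[, i] -
                          sub$values[i] * sub$vectors[, i])), 1e-8)
    expect_equal(crossprod(sub$vectors), diag(3), tolerance = 1e-10)
  }
})

test_that("bond constants recover spring constants, convert and double", {
  lin <- make_ideal_complex("linear")
  m <- spring_model(lin$geometry, lin$topology, k_bond = 0.25, k_perp = 0.01)
  h <- make_spring_hessian(m)
  bp <- bond_force_constant(h, lin$geometry, 1, 2)
  expect_equal(bp$k_raw, 0.25, tolerance = 1e-12)
  factor <- 2 * 627.509474 / 0.529177211^2
  expect_equal(bp$k_out, factor * 0.25, tolerance = 1e-12)
  expect_equal(factor / 2, 2240.88, tolerance = 1e-5)
  expect_equal(bp$r_eq, 2.30)
  # swap symmetry
  bp2 <- bond_force_constant(h, lin$geometry, 2, 1)
  expect_equal(bp2$k_out, bp$k_out)
  expect_equal(bp2$r_eq, bp$r_eq)
})

test_that("a bond axis orthogonal to the stiff mode gives zero stiffness", {
  # hand-built Hessian whose interaction block is stiff along y only,
  # while the bond lies along x
  g <- geometry(c("Hg", "Cl"), rbind(c(0, 0, 0), c(2.3, 0, 0)))
  block <- 0.3 * diag(c(0, 1, 0))
  h <- matrix(0, 6, 6)
  h[1:3, 4:6] <- -block
  h[4:6, 1:3] <- -block
  h[1:3, 1:3] <- h[4:6, 4:6] <- block
  bp <- suppressWarnings(
    bond_force_constant(cartesian_hessian(h, 2L), g, 1, 2))
  expect_equal(bp$k_raw, 0)
  expect_false(bp$stable)
})

test_that("angle constants match the closed form on anisotropic planar stars", {
  for (seed in c(2, 9, 23)) {
    star <- random_planar_star(4, seed = seed)
    for (k in seq_len(nrow(star$topology$angles))) {
      a <- star$topology$angles[k, ]
      ap <- angle_force_constant(star$hessian, star$geometry,
                                 a[1], a[2], a[3])
      expect_equal(ap$k_theta_out,
                   star_angle_closed_form(star, a[1], a[2], a[3]),
                   tolerance = 1e-10)
      # construction invariants of the perpendicular unit vectors
      expect_lt(abs(sum(ap$u_PA * ap$u_AB)), 1e-10)
      expect_lt(abs(sum(ap$u_PC * ap$u_CB)), 1e-10)
      expect_lt(abs(sum(ap$u_N * ap$u_AB)), 1e-10)
      expect_lt(abs(sum(ap$u_N * ap$u_CB)), 1e-10)
      # A <-> C exchange symmetry
      ap_rev <- angle_force_constant(star$hessian, star$geometry,
                                     a[3], a[2], a[1])
      expect_equal(ap_rev$k_theta_out, ap$k_theta_out, tolerance = 1e-12)
    }
  }
})

test_that("collinear triads error by default and fall back when asked", {
  lin <- make_ideal_complex("linear")
  m <- spring_model(lin$geometry, lin$topology, k_bond = 0.3, k_perp = 0.05)
  h <- make_spring_hessian(m)
  expect_error(angle_force_constant(h, lin$geometry, 2, 1, 3), "collinear")
  ap <- angle_force_constant(h, lin$geometry, 2, 1, 3,
                             on_linear = "fallback")
  expect_true(ap$degenerate)
  expect_equal(ap$theta_eq, 180)
  expect_gt(ap$k_theta_out, 0)
})

test_that("rotating the system leaves every force constant unchanged", {
  set.seed(77)
  star <- random_planar_star(5, seed = 13)
  ref_bonds <- vapply(seq_len(nrow(star$topology$bonds)), function(k)
    bond_force_constant(star$hessian, star$geometry,
                        star$topology$bonds[k, 1], star$topology$bonds[k, 2])$k_out,
    numeric(1))
  ref_angles <- vapply(seq_len(nrow(star$topology$angles)), function(k) {
    a <- star$topology$angles[k, ]
    angle_force_constant(star$hessian, star$geometry, a[1], a[2], a[3])$k_theta_out
  }, numeric(1))
  for (rep in 1:3) {
    rot <- random_rotation()
    sys <- rotate_system(star$geometry, star$hessian, rot)
    got_b <- vapply(seq_len(nrow(star$topology$bonds)), function(k)
      bond_force_constant(sys$hessian, sys$geometry,
                          star$topology$bonds[k, 1], star$topology$bonds[k, 2])$k_out,
      numeric(1))
    got_a <- vapply(seq_len(nrow(star$topology$angles)), function(k) {
      a <- star$topology$angles[k, ]
      angle_force_constant(sys$hessian, sys$geometry, a[1], a[2], a[3])$k_theta_out
    }, numeric(1))
    expect_equal(got_b, ref_bonds, tolerance = 1e-8)
    expect_equal(got_a, ref_angles, tolerance = 1e-8)
  }
})

test_that("whole-molecule runs tag metal terms and keep spring constants positive", {
  oct <- make_ideal_complex("octahedral")
  m <- spring_model(oct$geometry, oct$topology, k_bond = 0.25, k_perp = 0.05)
  sem <- all_metal_parameters(make_spring_hessian(m), oct$geometry,
                              oct$topology)
  expect_length(sem$bonds, 6L)
  expect_length(sem$angles, 15L)
  expect_true(all(vapply(sem$bonds, `[[`, logical(1), "involves_metal")))
  expect_true(all(vapply(sem$angles, `[[`, logical(1), "involves_metal")))
  expect_true(all(vapply(sem$bonds, `[[`, numeric(1), "k_out") >= 0))
  expect_true(all(vapply(sem$angles, `[[`, numeric(1), "k_theta_out") >= 0))
  # trans angles flagged degenerate, cis angles not
  degen <- vapply(sem$angles, `[[`, logical(1), "degenerate")
  theta <- vapply(sem$angles, `[[`, numeric(1), "theta_eq")
  expect_equal(sum(degen), 3L)
  expect_true(all(abs(theta[!degen] - 90) < 1e-8))

  eth <- ethane_geometry()
  top_e <- build_topology(eth, require_metal = FALSE)
  m_e <- spring_model(eth, top_e, k_bond = 0.3, k_perp = 0.05)
  sem_e <- all_metal_parameters(make_spring_hessian(m_e), eth, top_e)
  expect_false(any(vapply(sem_e$bonds, `[[`, logical(1), "involves_metal")))
  expect_false(any(vapply(sem_e$angles, `[[`, logical(1), "involves_metal")))
})
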