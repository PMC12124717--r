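# Equivalence classes and the constrained restrained-ESP fit.

test_that("neighborhood refinement partitions symmetric molecules correctly", {
  wat <- water_geometry()
  top_w <- build_topology(wat, require_metal = FALSE)
  cls <- equivalence_classes(top_w, wat)
  expect_equal(cls, list(1L, c(2L, 3L)))

  oct <- make_ideal_complex("octahedral")
  cls_o <- equivalence_classes(oct$topology, oct$geometry)
  expect_equal(cls_o, list(1L, 2:7))

  # type-based colors split ULS-labeled donors into singletons
  asg <- apply_uls(assign_base_types(oct$geometry, oct$topology),
                   oct$topology)
  cls_t <- equivalence_classes(oct$topology, oct$geometry,
                               assignment = asg, use_types = TRUE)
  expect_length(cls_t, 7L)

  # ethane: 2 equivalent carbons, 6 equivalent hydrogens
  eth <- ethane_geometry()
  cls_e <- equivalence_classes(build_topology(eth, require_metal = FALSE),
                               eth)
  expect_equal(lengths(cls_e), c(2L, 6L))
})

test_that("zero-restraint fit recovers the generating charges exactly", {
  oct <- make_ideal_complex("octahedral")
  truth <- c(0.8, 0.35, 0.15, 0.25, 0.10, 0.30, 0.05)
  expect_equal(sum(truth), 2)
  grid <- make_esp_grid(oct$geometry, truth, 80, seed = 17)
  fit <- fit_charges(oct$geometry, grid,
                     restraint_spec(2L, strength = 0))
  expect_equal(fit$charges, truth, tolerance = 1e-6)
  expect_equal(sum(fit$charges), 2, tolerance = 1e-12)
  # doubling the grid does not move the recovered charges
  grid2 <- make_esp_grid(oct$geometry, truth, 160, seed = 18)
  fit2 <- fit_charges(oct$geometry, grid2,
                      restraint_spec(2L, strength = 0))
  expect_equal(fit2$charges, fit$charges, tolerance = 1e-6)
})

test_that("fixed charges and equivalence classes hold exactly in the fit", {
  oct <- make_ideal_complex("octahedral")
  truth <- c(0.5, rep(0.25, 6))
  grid <- make_esp_grid(oct$geometry, truth, 80, seed = 23)
  spec <- restraint_spec(2L, fixed = c("1" = 1.45),
                         classes = list(1L, 2:7))
  fit <- fit_charges(oct$geometry, grid, spec)
  expect_identical(fit$charges[1], 1.45)
  expect_equal(sum(fit$charges), 2, tolerance = 1e-12)
  expect_equal(max(fit$charges[2:7]) - min(fit$charges[2:7]), 0)
  expect_equal(fit$method_tag, "resp")
})

test_that("restrained fits converge and shrink toward smaller magnitudes", {
  oct <- make_ideal_complex("octahedral")
  truth <- c(0.8, 0.35, 0.15, 0.25, 0.10, 0.30, 0.05)
  grid <- make_esp_grid(oct$geometry, truth, 80, seed = 29)
  free <- fit_charges(oct$geometry, grid, restraint_spec(2L, strength = 0))
  tight <- fit_charges(oct$geometry, grid,
                       restraint_spec(2L, strength = 0.01))
  expect_equal(sum(tight$charges), 2, tolerance = 1e-12)
  expect_lt(sum(abs(tight$charges)), sum(abs(free$charges)) + 1e-12)
  # two-stage variant also conserves charge and honours classes
  two <- fit_charges(oct$geometry, grid,
                     restraint_spec(2L, classes = list(1L, 2:7)),
                     two_stage = TRUE)
  expect_equal(sum(two$charges), 2, tolerance = 1e-12)
  expect_equal(max(two$charges[2:7]) - min(two$charges[2:7]), 0)
})

test_that("infeasible or malformed restraints are rejected", {
  oct <- make_ideal_complex("octahedral")
  grid <- make_esp_grid(oct$geometry, c(0.8, rep(0.2, 6)), 60, seed = 5)
  expect_error(
    fit_charges(oct$geometry, grid,
                restraint_spec(2L, fixed = c("1" = 0.5, "9" = 0.1))),
    "out of range")
  spec_conflict <- restraint_spec(2L, fixed = c("2" = 0.1, "3" = 0.4),
                                  classes = list(2:3))
  expect_error(fit_charges(oct$geometry, grid, spec_conflict),
               "conflicting")
  expect_error(restraint_spec(2L, strength = -1), ">= 0")
  expect_error(restraint_spec(0.3), "integer")
})

test_that("ESP grid and constraint files round-trip through their readers", {
  oct <- make_ideal_complex("octahedral")
  grid <- make_esp_grid(oct$geometry, c(0.8, rep(0.2, 6)), 60, seed = 7)
  gp <- withr::local_tempfile(fileext = ".esp")
  write_esp_grid(grid, gp)
  grid2 <- read_esp_grid(gp)
  expect_equal(grid2$points, grid$points, tolerance = 1e-9)
  expect_equal(grid2$potentials, grid$potentials, tolerance = 1e-9)

  cp <- withr::local_tempfile(fileext = ".cons")
  writeLines(c("# impose the metal charge", "1 1.45", "total 2"), cp)
  cons <- read_constraints(cp, n_atoms = 7L)
  expect_equal(cons$fixed, c("1" = 1.45))
  expect_equal(cons$total_charge, 2)
  writeLines(c("9 0.1", "total 2"), cp)
  expect_error(read_constraints(cp, n_atoms = 7L), "out of range")
  writeLines("1 0.5", cp)
  expect_error(read_constraints(cp), "total")
})
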