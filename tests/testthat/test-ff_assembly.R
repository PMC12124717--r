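# Database parsing, merge rules, provenance bookkeeping and the UFF metal
# Lennard-Jones convention.

test_that("frcmod parsing builds canonical, direction-free lookups", {
  path <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c("test database", "MASS", "ca 12.011", "",
               "BOND", "ca-ca  478.40   1.387", "ca-nb  483.10   1.342",
               "", "ANGLE", "ca-ca-nb   68.80     117.22",
               "", "DIHE", "ca-ca-ca-ca   1    3.625       180.0    2.0",
               "", "IMPROPER", "", "NONBON", "  ca  1.9080  0.0860"), path)
  db <- load_parameter_database(path)
  expect_equal(database_lookup(db, c("ca", "ca"), "bond"),
               list(k = 478.40, r_eq = 1.387))
  expect_equal(database_lookup(db, c("nb", "ca"), "bond"),
               database_lookup(db, c("ca", "nb"), "bond"))
  expect_equal(database_lookup(db, c("nb", "ca", "ca"), "angle")$theta_eq,
               117.22)
  expect_null(database_lookup(db, c("zz", "zz"), "bond")) # miss, not error
  expect_equal(db$nonbon[["ca"]]$rmin_half, 1.9080)
  expect_equal(db$mass[["ca"]], 12.011)
  expect_equal(db$dihedrals[["ca-ca-ca-ca"]][[1]]$pn, 2)
})

test_that("the shipped example database parses and resolves aromatic keys", {
  db <- load_parameter_database(
    system.file("extdata", "gaff_subset.frcmod", package = "metalff"))
  expect_equal(database_lookup(db, c("ca", "ca"), "bond")$k, 478.40)
  expect_equal(database_lookup(db, c("nb", "ca", "ca"), "angle")$theta_eq,
               117.22)
  expect_equal(db$mass[["nb"]], 14.007)
})

test_that("malformed database records name the offending line", {
  path <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c("bad", "BOND", "ca-ca-ca 478.40 1.387"), path)
  expect_error(load_parameter_database(path), "line 3")
})

test_that("UFF metal LJ halves the vdW distance and keeps the well depth", {
  e <- metal_lj("Ru")
  expect_equal(e$rmin_half, 2.963 / 2)
  expect_equal(e$eps, 0.056)
  e2 <- metal_lj("Hg")
  expect_equal(e2$rmin_half, 2.705 / 2)
  expect_equal(e2$eps, 0.385)
  expect_error(metal_lj("Zz"), "not in the embedded UFF")
})

test_that("merge rules: metal terms Seminario, database hits win elsewhere, misses fall back", {
  oct <- make_ideal_complex("octahedral")
  asg <- apply_uls(assign_base_types(oct$geometry, oct$topology),
                   oct$topology)
  m <- spring_model(oct$geometry, oct$topology, k_bond = 0.25, k_perp = 0.05)
  sem <- all_metal_parameters(make_spring_hessian(m), oct$geometry,
                              oct$topology)
  empty_db <- structure(list(bonds = list(), angles = list(),
                             dihedrals = list(), nonbon = list(),
                             mass = list()), class = "ff_database")
  ps <- assemble_parameters(oct$topology, asg, sem, oct$geometry,
                            database = empty_db)
  expect_true(all(vapply(ps$bonds, `[[`, character(1), "provenance") ==
                    "seminario"))
  expect_true(all(vapply(ps$angles, `[[`, character(1), "provenance") ==
                    "seminario"))
  expect_equal(ps$lj[["Ru"]]$provenance, "uff")
  expect_equal(ps$lj[["Ru"]]$rmin_half, 2.963 / 2)

  # organic scaffold: hit in the database vs Seminario fallback
  eth <- ethane_geometry()
  top <- build_topology(eth, require_metal = FALSE)
  asg_e <- assign_base_types(eth, top)
  m_e <- spring_model(eth, top, k_bond = 0.3, k_perp = 0.05)
  sem_e <- all_metal_parameters(make_spring_hessian(m_e), eth, top)
  ps_hit <- assemble_parameters(top, asg_e, sem_e, eth)
  expect_equal(ps_hit$bonds[["c4-h1"]]$provenance, "database")
  expect_equal(ps_hit$bonds[["c4-h1"]]$k, 337.30)
  ps_miss <- assemble_parameters(top, asg_e, sem_e, eth,
                                 database = empty_db)
  expect_equal(ps_miss$bonds[["c4-h1"]]$provenance, "seminario")
  expect_true(any(grepl("bond c4-h1", ps_miss$missing)))
})

test_that("metal dihedrals are single zero-barrier terms", {
  tb <- make_ideal_complex("tris_bidentate")
  asg <- apply_uls(assign_base_types(tb$geometry, tb$topology),
                   tb$topology)
  m <- spring_model(tb$geometry, tb$topology, k_bond = 0.25, k_perp = 0.05)
  sem <- all_metal_parameters(make_spring_hessian(m), tb$geometry,
                              tb$topology)
  ps <- assemble_parameters(tb$topology, asg, sem, tb$geometry)
  metal_keys <- vapply(seq_len(nrow(tb$topology$dihedrals)), function(k) {
    term <- tb$topology$dihedrals[k, ]
    if (any(term %in% tb$topology$metal_indices))
      parameter_key(term, asg) else NA_character_
  }, character(1))
  metal_keys <- unique(metal_keys[!is.na(metal_keys)])
  for (key in metal_keys) {
    e <- ps$dihedrals[[key]]
    expect_equal(e$provenance, "zeroed")
    expect_length(e$terms, 1L)
    expect_equal(e$terms[[1]]$pk, 0)
    expect_equal(e$terms[[1]]$pn, 1)
    expect_equal(e$terms[[1]]$phase, 0)
  }
})

test_that("assembled entries exactly cover the topology with disjoint provenance", {
  for (kind in c("octahedral", "square_planar", "linear", "bimetallic",
                 "tris_bidentate")) {
    cx <- make_ideal_complex(kind)
    asg <- apply_uls(assign_base_types(cx$geometry, cx$topology),
                     cx$topology)
    m <- spring_model(cx$geometry, cx$topology, k_bond = 0.25,
                      k_perp = 0.05)
    sem <- all_metal_parameters(make_spring_hessian(m), cx$geometry,
                                cx$topology)
    ps <- assemble_parameters(cx$topology, asg, sem, cx$geometry)
    bond_keys <- unique(apply(cx$topology$bonds, 1, parameter_key,
                              assignment = asg))
    angle_keys <- if (nrow(cx$topology$angles))
      unique(apply(cx$topology$angles, 1, parameter_key,
                   assignment = asg)) else character(0)
    expect_setequal(names(ps$bonds), bond_keys)
    expect_setequal(names(ps$angles), angle_keys)
    dihedral_keys <- if (nrow(cx$topology$dihedrals))
      unique(apply(cx$topology$dihedrals, 1, parameter_key,
                   assignment = asg)) else character(0)
    expect_equal(length(ps$dihedrals), length(dihedral_keys), label = kind)
    # one provenance per entry, from the closed vocabulary
    provs <- c(vapply(ps$bonds, `[[`, character(1), "provenance"),
               vapply(ps$angles, `[[`, character(1), "provenance"),
               vapply(ps$dihedrals, `[[`, character(1), "provenance"),
               vapply(ps$lj, `[[`, character(1), "provenance"))
    expect_true(all(provs %in% c("seminario", "database", "uff", "zeroed")))
  }
})
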