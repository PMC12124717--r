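# frcmod/mol2/PDB emission: round trips, fixed-column conventions and byte
# determinism.

octahedral_params <- function() {
  oct <- make_ideal_complex("octahedral")
  asg <- apply_uls(assign_base_types(oct$geometry, oct$topology),
                   oct$topology)
  m <- spring_model(oct$geometry, oct$topology, k_bond = 0.25,
                    k_perp = 0.05)
  sem <- all_metal_parameters(make_spring_hessian(m), oct$geometry,
                              oct$topology)
  oct$geometry$total_charge <- 2L
  qs <- charge_set(c(0.8, rep(0.2, 6)))
  list(cx = oct, asg = asg,
       ps = assemble_parameters(oct$topology, asg, sem, oct$geometry,
                                charges = qs),
       charges = qs)
}

test_that("frcmod records carry the stated values and re-parse at printed precision", {
  fx <- octahedral_params()
  path <- withr::local_tempfile(fileext = ".frcmod")
  write_frcmod(fx$ps, path)
  text <- readLines(path)
  expect_true(any(grepl("^MASS", text)))
  for (sec in c("BOND", "ANGLE", "DIHE", "IMPROPER", "NONBON"))
    expect_true(any(grepl(paste0("^", sec), text)))
  # a known bond line: k = 2 x 2240.877 x 0.25, r_eq = 2.10
  bond_line <- grep("^N1-Ru ", text, value = TRUE)
  expect_length(bond_line, 1L)
  expect_match(bond_line, "1120\\.439")
  expect_match(bond_line, "2\\.1000")

  db <- load_parameter_database(path)
  for (key in names(fx$ps$bonds)) {
    expect_equal(db$bonds[[key]]$k, round(fx$ps$bonds[[key]]$k, 3))
    expect_equal(db$bonds[[key]]$r_eq, round(fx$ps$bonds[[key]]$r_eq, 4))
  }
  for (key in names(fx$ps$angles)) {
    expect_equal(db$angles[[key]]$k, round(fx$ps$angles[[key]]$k, 3))
    expect_equal(db$angles[[key]]$theta_eq,
                 round(fx$ps$angles[[key]]$theta_eq, 3))
  }
  for (ty in names(fx$ps$lj)) {
    expect_equal(db$nonbon[[ty]]$rmin_half,
                 round(fx$ps$lj[[ty]]$rmin_half, 4))
    expect_equal(db$nonbon[[ty]]$eps, round(fx$ps$lj[[ty]]$eps, 4))
  }
})

test_that("zero-barrier metal dihedrals are encoded as PK=0, PN=1, PHASE=0", {
  tb <- make_ideal_complex("tris_bidentate")
  asg <- apply_uls(assign_base_types(tb$geometry, tb$topology),
                   tb$topology)
  m <- spring_model(tb$geometry, tb$topology, k_bond = 0.25, k_perp = 0.05)
  sem <- all_metal_parameters(make_spring_hessian(m), tb$geometry,
                              tb$topology)
  ps <- assemble_parameters(tb$topology, asg, sem, tb$geometry)
  text <- strsplit(write_frcmod(ps), "\n")[[1]]
  dihe_start <- grep("^DIHE", text)
  impr_start <- grep("^IMPROPER", text)
  dihe_lines <- text[(dihe_start + 1):(impr_start - 2)]
  expect_gt(length(dihe_lines), 0)
  expect_true(all(grepl("0\\.000\\s+0\\.000\\s+1\\.0\\s+SCEE", dihe_lines)))
})

test_that("an empty parameter set refuses to write", {
  empty <- structure(list(bonds = list(), angles = list(),
                          dihedrals = list(), lj = list(), masses = list(),
                          metal_types = character(0)),
                     class = "ff_parameter_set")
  expect_error(write_frcmod(empty), "nothing to write")
})

test_that("mol2 blocks count atoms/bonds and round-trip the charges", {
  fx <- octahedral_params()
  path <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(fx$cx$geometry, fx$cx$topology, fx$asg, fx$charges,
             path = path)
  text <- readLines(path)
  atom_i <- grep("^@<TRIPOS>ATOM", text)
  bond_i <- grep("^@<TRIPOS>BOND", text)
  expect_equal(bond_i - atom_i - 1L, 7L)          # 7 ATOM records
  expect_equal(length(text) - bond_i, 6L)         # 6 BOND records
  # ULS types appear in the atom-type column
  expect_true(any(grepl(" N1 ", text[(atom_i + 1):(bond_i - 1)])))
  cs <- read_charges(path, "mol2", geom = fx$cx$geometry)
  expect_equal(cs$charges, fx$charges$charges, tolerance = 1e-6)
  expect_equal(sum(cs$charges), 2, tolerance = 1e-4)
})

test_that("PDB HETATM records follow the v3.3 column conventions", {
  g <- water_geometry()
  text <- strsplit(write_pdb(g), "\n")[[1]]
  expect_equal(sum(grepl("^HETATM", text)), 3L)

  oct <- make_ideal_complex("octahedral")
  lines <- strsplit(write_pdb(oct$geometry), "\n")[[1]]
  ru <- lines[1]
  expect_equal(substr(ru, 77, 78), "RU")            # element right-justified
  expect_equal(substr(ru, 13, 14), "Ru")            # 2-char name from col 13
  n1 <- lines[2]
  expect_equal(substr(n1, 13, 14), " N")            # 1-char name from col 14
  # coordinates printed to 3 decimals in fixed columns
  expect_equal(as.numeric(substr(n1, 31, 38)), 2.100)
  expect_equal(as.numeric(substr(n1, 39, 46)), 0)
})

test_that("bio3d re-reads the written PDB with identical coordinates", {
  library(bio3d)
  oct <- make_ideal_complex("octahedral")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(oct$geometry, path = path)
  pdb <- bio3d::read.pdb(path)
  expect_equal(nrow(pdb$atom), 7L)
  expect_equal(matrix(pdb$xyz, ncol = 3, byrow = TRUE),
               oct$geometry$coordinates, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(trimws(pdb$atom$elesy), toupper(oct$geometry$elements))
})

test_that("writers are byte-deterministic and the lib file lists atoms and bonds", {
  fx <- octahedral_params()
  expect_identical(write_frcmod(fx$ps), write_frcmod(fx$ps))
  expect_identical(
    write_mol2(fx$cx$geometry, fx$cx$topology, fx$asg, fx$charges),
    write_mol2(fx$cx$geometry, fx$cx$topology, fx$asg, fx$charges))
  expect_identical(write_pdb(fx$cx$geometry), write_pdb(fx$cx$geometry))
  lib <- strsplit(write_lib(fx$cx$geometry, fx$cx$topology, fx$asg,
                            fx$charges), "\n")[[1]]
  expect_equal(sum(grepl("^ \"", lib)) - 1L, 7L)   # unit name + 7 atoms
  expect_equal(sum(grepl("^ \\d+ \\d+ 1$", lib)), 6L)
})
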