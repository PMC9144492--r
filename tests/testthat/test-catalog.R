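test_that("solvent catalogs round-trip through CSV with de-scaled EI columns", {
  solvents <- example_solvents()
  expect_equal(nrow(solvents), 4)
  # scaled headers are de-scaled at load: HTPIng x10, ATP x1e5
  dmso <- solvents[solvents$name == "DMSO", ]
  expect_equal(dmso$htping, 0.130)
  expect_equal(dmso$atp, 6.20e-5)
  expect_equal(dmso$pcop, 11.40)
  # water carries no EI block
  expect_true(is.na(solvents$htping[solvents$name == "water"]))

  tmp <- tempfile(fileext = ".csv")
  write_solvent_catalog(solvents, tmp)
  back <- read_solvent_catalog(tmp)
  expect_equal(back$name, solvents$name)
  expect_equal(back$molar_mass, solvents$molar_mass, tolerance = 1e-12)
  expect_equal(back$htping, solvents$htping, tolerance = 1e-12)

  # de-scaling then re-scaling is the identity
  tmp2 <- tempfile(fileext = ".csv")
  write_solvent_catalog(solvents, tmp2, scaled = TRUE)
  rescaled <- read_solvent_catalog(tmp2)
  expect_equal(rescaled$htping, solvents$htping, tolerance = 1e-12)
  expect_equal(rescaled$atp, solvents$atp, tolerance = 1e-12)
})

test_that("catalog schema and row-level validation fail loudly", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("name,cas,available\nfoo,1-2-3,TRUE", tmp)
  expect_error(read_solvent_catalog(tmp), "molar_mass_g_mol")

  writeLines("name,cas,molar_mass_g_mol,available,htping,htpinh,ttp,atp,gwp,odp,pcop,ar
foo,1-2-3,50,TRUE,0.1,0.1,0.1,oops,0,0,0,0", tmp)
  expect_error(read_solvent_catalog(tmp), "row 1")

  writeLines("name,cas,molar_mass_g_mol,available\nfoo,1-2-3,-1,TRUE", tmp)
  expect_error(read_solvent_catalog(tmp), "molar_mass")
})

test_that("fusion-enthalpy conversion applies the exact calorie factor", {
  expect_identical(convert_fusion_enthalpy(20.9, "kJ/mol"), 20.9)
  expect_identical(convert_fusion_enthalpy(1.0, "kcal/mol"), 4.184)
  expect_equal(convert_fusion_enthalpy(20.9, "kcal/mol"), 87.4456)
  expect_error(convert_fusion_enthalpy(20.9, "J/mol"), "unit")
  expect_error(convert_fusion_enthalpy(-1, "kJ/mol"))
})

test_that("solute catalog stores kelvin melting points and kJ/mol enthalpies", {
  solutes <- example_solutes()
  benz <- solutes[solutes$name == "benzamide", ]
  expect_equal(benz$tm, 401.0)
  expect_equal(benz$hfus, 20.9)
  # a kcal-tagged file is converted on load
  tmp <- tempfile(fileext = ".csv")
  writeLines("name,cas,tm_K,hfus,hfus_unit\nX,0,300,1.0,kcal/mol", tmp)
  expect_equal(read_solute_catalog(tmp)$hfus, 4.184)
})

test_that("solute-free fraction excludes the solute from the basis", {
  expect_equal(solute_free_fraction(1, 4), 0.2)
  expect_equal(solute_free_fraction(1, 0), 1.0)
  expect_equal(solute_free_fraction(3, 2), 0.6)
  expect_error(solute_free_fraction(0, 0), "zero")
  expect_error(solute_free_fraction(-1, 1))
})

test_that("measurement records read, validate and round-trip", {
  path <- system.file("extdata", "salicylamide_4fm_synthetic.csv",
                      package = "greensolv")
  m <- read_measurements(path)
  expect_equal(nrow(m), 6)
  expect_equal(lengths(m$replicates), rep(3L, 6))
  expect_equal(m$x_mean[m$organic_fraction == 0.6], 0.379)

  tmp <- tempfile(fileext = ".csv")
  write_measurements(m, tmp)
  back <- read_measurements(tmp)
  expect_equal(back$x_mean, m$x_mean, tolerance = 1e-12)
  expect_equal(back$replicates, m$replicates, tolerance = 1e-12)

  writeLines("solute,organic_solvent,x2_star,T_K,x_rep1\nX,Y,1.5,298.15,0.1", tmp)
  expect_error(read_measurements(tmp), "\\[0, 1\\]")
  writeLines("solute,organic_solvent,x2_star,T_K,x_rep1\nX,Y,0.5,298.15,1.2", tmp)
  expect_error(read_measurements(tmp), "\\(0, 1\\)")
})
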