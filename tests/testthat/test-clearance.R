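test_that("hepatic Vmax scaling reproduces the unit-chain oracle", {
  # frozen oracle: 3.37*137*45*(1.47*1000)*3.92*60*277.4e-9 computed
  # independently (spreadsheet-style chain)
  expect_equal(scale_hepatic_vmax(3.37, 137, 45, 1.47, 3.92, 277.4),
               1992.6181906949, tolerance = 1e-10)
  expect_equal(scale_hepatic_vmax(0, 137, 45, 1.47, 3.92, 277.4), 0)
  # unit inputs: 1 pmol/min/pmol * 1 pmol/mg * 1 mg/g * 1 g * 60 * 1000 g/mol
  expect_equal(scale_hepatic_vmax(1, 1, 1, 0.001, 1, 1000), 6e-5)
  expect_error(scale_hepatic_vmax(1, 0, 45, 1.47, 1, 277.4), "positive")
})

test_that("Vmax is invariant to volume-vs-mass liver representation", {
  # density 1 g/mL: volume [L] and mass [kg] carry the same number
  v1 <- scale_hepatic_vmax(3.97, 73, 45, 1.47, 5.73, 277.4)
  v2 <- 3.97 * 73 * 45 * 1470 * 5.73 * 60 * 277.4 * 1e-9  # mass-form chain
  expect_equal(v1, v2)
})

test_that("Km converts from uM to mg/L through the molecular weight", {
  expect_equal(km_to_mass_units(213.8, 277.4), 59.30812)
  expect_equal(km_to_mass_units(8.52, 277.4), 2.363448)
  expect_equal(km_to_mass_units(1000, 1000), 1000)
  expect_error(km_to_mass_units(0, 277.4), "positive")
})

test_that("cardiac per-isoform clearance follows the per-mg chain", {
  # CYP2C8: 0.072 uL/min/pmol * 0.2 pmol/mg = 0.0144 uL/min/mg
  expect_equal(cardiac_intrinsic_clearance(0.072, 0.2, 11732),
               0.0144 * 11732 * 60 * 1e-6)
  # CYP2C9: 0.079 * 5.5 = 0.4345 uL/min/mg
  expect_equal(cardiac_intrinsic_clearance(0.079, 5.5, 11732),
               0.4345 * 11732 * 60 * 1e-6)
  # CYP2J2 carries no amitriptyline clearance
  expect_equal(cardiac_intrinsic_clearance(0, 0.17, 11732), 0)
  # fu_mic scales the unbound clearance up
  expect_equal(cardiac_intrinsic_clearance(0.072, 0.2, 11732, fu_mic = 0.5),
               2 * cardiac_intrinsic_clearance(0.072, 0.2, 11732))
})

test_that("total cardiac clearance reproduces the published 0.316 L/h", {
  clu <- cardiac_intrinsic_clearance(c(0.072, 0.079, 0), c(0.2, 5.5, 0.17),
                                     11732)
  tot <- total_cardiac_clearance(clu, q_he = 15.59952, fu_p = 0.05, bp = 1.04)
  expect_equal(tot$clu_int, 0.315989688, tolerance = 1e-9)
  expect_equal(round(tot$clu_int, 3), 0.316)
  # frozen well-stirred companion value
  expect_equal(tot$clm_ht, 0.0151770315575, tolerance = 1e-9)
})

test_that("clearance linearity and the well-stirred flow bound hold", {
  abund <- c(0.2, 5.5, 0.17)
  base <- cardiac_intrinsic_clearance(c(0.072, 0.079, 0), abund, 11732)
  dbl <- cardiac_intrinsic_clearance(2 * c(0.072, 0.079, 0), abund, 11732)
  expect_equal(sum(dbl), 2 * sum(base))
  q_he <- 15.59952
  for (clu in c(0, 0.316, 10, 1e4, 1e8)) {
    clm <- total_cardiac_clearance(clu, q_he, 0.05, 1.04)$clm_ht
    expect_lt(clm, q_he)
    expect_gte(clm, 0)
  }
  # flow-limited asymptote
  expect_equal(total_cardiac_clearance(1e12, q_he, 0.05, 1.04)$clm_ht, q_he,
               tolerance = 1e-6)
  # empty isoform list is a valid no-metabolism heart
  expect_equal(total_cardiac_clearance(numeric(0), q_he, 0.05, 1.04),
               list(clu_int = 0, clm_ht = 0))
})

test_that("clearance_set assembles whole-organ values from the model", {
  m <- default_model()
  cs <- clearance_set(m)
  expect_named(cs$hepatic_vmax, default_hepatic_enzymes()$isoform)
  expect_equal(cs$hepatic_vmax[["CYP3A4"]], 1992.6181906949, tolerance = 1e-9)
  expect_equal(cs$hepatic_km[["CYP3A4"]], 59.30812)
  expect_equal(cs$clu_int_heart, 0.315989688, tolerance = 1e-9)
  expect_equal(cs$cl_renal, 0.504)
  # a missing liver abundance is a configuration error naming the isoform
  m$drug$enzymes$liver_abundance[m$drug$enzymes$isoform == "CYP2D6"] <- NA
  expect_error(clearance_set(m), "CYP2D6")
})
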