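test_that("elemental formulas assemble correctly for the main classes", {
  pc <- elemental_formula("PC", list(acyl_chain(16, 0), acyl_chain(18, 1)))
  expect_identical(evlipid:::format_formula(pc), "C42H82NO8P")

  sm <- elemental_formula("SM", list(acyl_chain(18, 1, "sphingoid-d"),
                                     acyl_chain(16, 0)))
  expect_identical(evlipid:::format_formula(sm), "C39H79N2O6P")

  # tetra-linoleoyl cardiolipin, a standard reference formula
  cl <- elemental_formula("CL", rep(list(acyl_chain(18, 2)), 4))
  expect_identical(evlipid:::format_formula(cl), "C81H142O17P2")

  # Avanti-style PE standard: formula mass must agree with the
  # independent element-sum oracle
  pe <- lipid_species("PE", c("12:0", "13:0"))
  expect_equal(pe$monoisotopic_mass,
               oracle_mass_from_string(evlipid:::format_formula(pe$formula)),
               tolerance = 1e-6)
})

test_that("invalid species are rejected", {
  expect_error(lipid_species("LPC", "0:0"), "invalid-species")
  expect_error(elemental_formula("TG", list(acyl_chain(16, 0))),
               "unsupported-class")
  expect_error(lipid_species("LPC", c("16:0", "18:1")), "invalid-species")
  expect_error(lipid_species("PC", c("d18:1", "16:0")), "invalid-species")
  expect_error(lipid_species("SM", c("16:0", "18:1")), "invalid-species")
  expect_error(acyl_chain(16, 9), "double bonds")
})

test_that("monoisotopic mass is an element sum with standard table", {
  expect_equal(monoisotopic_mass(c(H = 2, O = 1)), 18.0106, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(c()), 0.0)
  expect_equal(monoisotopic_mass(c(C = 42, H = 82, N = 1, O = 8, P = 1)),
               759.5778, tolerance = 1e-3)
  expect_error(monoisotopic_mass(c(Zz = 1)), "unsupported element")
  # additivity
  a <- c(C = 3, H = 8, O = 3); b <- c(H = 3, O = 4, P = 1)
  expect_equal(monoisotopic_mass(evlipid:::formula_sum(a, b)),
               monoisotopic_mass(a) + monoisotopic_mass(b))
})

test_that("precursor m/z applies the proton-mass convention", {
  pc <- lipid_species("PC", c("16:0", "18:1"))
  expect_equal(precursor_mz(759.5778, "[M+H]+"), 760.5851, tolerance = 1e-4)
  expect_equal(precursor_mz(759.5778, "[M-H]-"), 758.5705, tolerance = 1e-4)
  expect_equal(precursor_mz(pc, "[M+H]+") - precursor_mz(pc, "[M-H]-"),
               2 * PROTON_MASS, tolerance = 1e-6)
  expect_error(precursor_mz(pc, "[M+H]+", charge = 0), "charge")
  expect_error(precursor_mz(pc, "[M+2H]2+"), "unsupported adduct")
})

test_that("fragment prediction follows the canonical rule set", {
  pc <- lipid_species("PC", c("16:0", "18:1"))
  fr <- predict_fragments(pc, "positive", "[M+H]+")
  expect_true(any(abs(fr$mz - 184.0733) < 2e-4))  # phosphocholine
  expect_true(all(fr$mz > 0))
  expect_true(!is.unsorted(fr$mz))
  # neutral-loss ions sit below the precursor
  nl <- fr[grepl("^\\[M", fr$label), ]
  expect_true(all(nl$mz < precursor_mz(pc, "[M+H]+")))

  # lyso inventory is a subset of the diacyl one restricted to its chain
  lpc <- lipid_species("LPC", "16:0")
  pc2 <- lipid_species("PC", c("16:0", "16:0"))
  fr_l <- predict_fragments(lpc, "positive", "[M+H]+")
  expect_true(any(abs(fr_l$mz - 184.0733) < 2e-4))
  expect_lte(nrow(fr_l), nrow(predict_fragments(pc2, "positive", "[M+H]+")) + 1)

  # negative-mode carboxylates match the element-sum oracle
  pi_sp <- lipid_species("PI", c("17:0", "20:4"))
  fr_n <- predict_fragments(pi_sp, "negative", "[M-H]-")
  for (cd in list(c(17, 0), c(20, 4))) {
    expect_true(any(abs(fr_n$mz - oracle_carboxylate_mz(cd[1], cd[2])) < 1e-3))
  }
  expect_error(predict_fragments(pc, "positive", "[M-H]-"), "mismatch")
})

test_that("library masses all agree with the element-sum oracle", {
  lib <- build_lipid_library()
  expect_gt(nrow(lib), 500)
  oracle <- vapply(lib$formula, oracle_mass_from_string, numeric(1))
  expect_true(all(abs(lib$monoisotopic_mass - oracle) < 1e-4))
})

test_that("library generation is deterministic and sn-position agnostic", {
  lib1 <- build_lipid_library()
  lib2 <- build_lipid_library()
  expect_identical(as.data.frame(lib1), as.data.frame(lib2))
  expect_identical(lipid_species("PC", c("16:0", "18:1"))$name,
                   lipid_species("PC", c("18:1", "16:0"))$name)
})

test_that("library CSV round trip preserves species and masses", {
  lib <- build_lipid_library(species = list(
    lipid_species("PC", c("16:0", "18:1")),
    lipid_species("SM", c("d18:1", "16:0")),
    lipid_species("LPC", "16:0")
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lipid_library(lib, path)
  lib2 <- read_lipid_library(path)
  expect_equal(as.data.frame(lib2), as.data.frame(lib))
})
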