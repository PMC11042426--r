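# Composition parsing, residue masses, precursor/fragment arithmetic,
# and the diagnostic-ion registry.

test_that("composition strings parse and render canonically", {
  c1 <- parse_composition("Hex5HexNAc4Fuc1Neu5Ac2")
  expect_equal(unclass(c1)[c("hex", "hexnac", "dhex", "neu5ac")],
               c(hex = 5L, hexnac = 4L, dhex = 1L, neu5ac = 2L))
  expect_equal(format_composition(c1), "Hex5HexNAc4Fuc1Neu5Ac2")
  # Man5 alias and dHex/SO4/Sulf synonyms
  expect_equal(format_composition(parse_composition("Man5")), "Hex5HexNAc2")
  expect_equal(parse_composition("Hex3HexNAc2dHex1"),
               parse_composition("Hex3HexNAc2Fuc1"))
  expect_equal(parse_composition("HexNAc1Sulf1"),
               parse_composition("HexNAc1SO41"))
  # token without count means one
  expect_equal(format_composition(parse_composition("HexFuc")),
               "Hex1Fuc1")
  expect_error(parse_composition("Hex5Xyl2"), "Xyl")
  expect_error(parse_composition(""), "empty")
  expect_error(composition(neu5ac = 1, acetyl = 2), "acetyl")
})

test_that("parser round-trips over randomly generated compositions", {
  set.seed(11)
  for (i in 1:50) {
    counts <- c(hex = sample(0:12, 1), hexnac = sample(0:8, 1),
                dhex = sample(0:5, 1), neu5ac = sample(0:4, 1),
                neu5gc = sample(0:4, 1), hexa = sample(0:2, 1),
                sulfate = sample(0:2, 1))
    counts <- c(counts, acetyl = sample(0:(counts[["neu5ac"]] +
                                             counts[["neu5gc"]]), 1))
    if (sum(counts) == 0) counts[["hex"]] <- 1
    comp <- do.call(composition, as.list(counts))
    expect_identical(parse_composition(format_composition(comp)), comp)
  }
})

test_that("residue masses match the sum-of-atoms oracle", {
  expect_equal(residue_mass("Hex"), oracle_formula_mass(C = 6, H = 10, O = 5),
               tolerance = 1e-10)
  expect_equal(residue_mass("HexNAc"),
               oracle_formula_mass(C = 8, H = 13, N = 1, O = 5),
               tolerance = 1e-10)
  expect_equal(residue_mass("dHex"), oracle_formula_mass(C = 6, H = 10, O = 4),
               tolerance = 1e-10)
  expect_equal(residue_mass("Fuc"), residue_mass("dHex"))
  expect_equal(residue_mass("HexA"), oracle_formula_mass(C = 6, H = 8, O = 6),
               tolerance = 1e-10)
  expect_error(residue_mass("Pent"), "unknown")
})

test_that("reduced precursor masses reproduce printed one-decimal values", {
  cases <- list(
    list("Hex5HexNAc4Fuc1Neu5Ac2", 2371.9),
    list("Hex5HexNAc4Fuc1Neu5Gc2", 2403.9),
    list("Hex5HexNAc4Fuc1Neu5Ac1Neu5Gc1", 2387.9),
    list("Hex7HexNAc4Fuc1", 2113.8),
    list("Hex6HexNAc3Fuc1Neu5Ac1", 2039.7),
    list("Hex5HexNAc4Fuc1", 1789.7))
  for (cs in cases)
    expect_equal(round(precursor_mass(cs[[1]]), 1), cs[[2]])
  # single reduced hexose (the 183.0863 registry ion)
  expect_equal(precursor_mass("Hex1"), 183.0863, tolerance = 5e-5)
})

test_that("fragment masses follow B-ion / reduced-Y arithmetic", {
  expect_equal(fragment_mz("Hex1HexNAc1Fuc1"), 512.1974, tolerance = 1e-4)
  expect_equal(fragment_mz("HexNAc1"), 204.0867, tolerance = 1e-4)
  # reduced-end fragment vs independent oracle
  expect_equal(fragment_mz("Hex1HexNAc3", reduced_end = TRUE),
               oracle_mass(list(hex = 1, hexnac = 3), water = TRUE,
                           reduced = TRUE, protons = 1),
               tolerance = 1e-9)
  expect_error(fragment_mz(composition()), "empty")
})

test_that("fragment/precursor arithmetic is internally consistent", {
  set.seed(23)
  for (i in 1:25) {
    comp <- composition(hex = sample(1:9, 1), hexnac = sample(1:6, 1),
                        dhex = sample(0:3, 1), neu5ac = sample(0:3, 1))
    # non-reduced B ion vs reduced z=1 precursor differ by water + 2H
    expect_equal(precursor_mass(comp, reduced = TRUE, z = 1) -
                   fragment_mz(comp, reduced_end = FALSE),
                 18.010565 + 2.015650, tolerance = 1e-5)
    # charge-state consistency
    z2 <- precursor_mass(comp, reduced = TRUE, z = 2)
    z1 <- precursor_mass(comp, reduced = TRUE, z = 1)
    expect_equal(2 * z2 - 2 * 1.00727646688, z1 - 1.00727646688,
                 tolerance = 1e-9)
  }
  expect_error(precursor_mass("Man5", z = 0), "charge")
})

test_that("the built-in registry is complete and chemically consistent", {
  reg <- default_registry()
  expect_equal(nrow(reg), 49L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(reg$esnog_cutoff >= 0 & reg$esnog_cutoff <= 1))
  # feature assignments for the headline diagnostic ions
  lookup <- function(mz) reg$feature[which.min(abs(reg$mz - mz))]
  expect_equal(lookup(224.1118), "n_glycan")
  expect_equal(lookup(292.1027), "neu5ac")
  expect_equal(lookup(274.0921), "neu5ac")
  expect_equal(lookup(308.0976), "neu5gc")
  expect_equal(lookup(512.1974), "fucose_antenna")
  expect_equal(lookup(792.3234), "bisecting")
  expect_equal(lookup(528.1923), "alpha_gal")
  expect_equal(lookup(860.31427), "sda")
  expect_equal(lookup(622.1284), "hnk1_sulfo")
  # every stated composition reproduces its tabulated mass:
  # 0.002 amu for oxonium (B) ions, 0.005 amu for reduced-end ions
  has_comp <- nzchar(reg$composition)
  for (i in which(has_comp)) {
    calc <- fragment_mz(reg$composition[i], reduced_end = reg$reduced_end[i])
    tol <- if (reg$reduced_end[i]) 0.005 else 0.002
    expect_lt(abs(calc - reg$mz[i]), tol,
              label = paste0(reg$name[i], " |calc-tab|"))
  }
  # the n_glycan cut-off ships at the 0.03 operating point
  expect_equal(reg$esnog_cutoff[reg$feature == "n_glycan"], 0.03)
})

test_that("registry TSV round-trips through write/read", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(back$mz, reg$mz)
  expect_equal(back$composition, reg$composition)
  expect_equal(back$feature, reg$feature)
  expect_error(registry_ion(reg, "no_such_ion"), "matched 0")
  expect_equal(registry_ion(reg, 224.1118)$feature, "n_glycan")
})
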