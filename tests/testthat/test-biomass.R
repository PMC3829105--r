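mono <- monomerTable()

test_that("monomer table is internally consistent", {
  expect_true(all(mono$mass > 0))
  calc <- vapply(mono$formula, formulaMass, numeric(1))
  expect_true(all(abs(calc - mono$mass) / mono$mass < 0.001))
  ## the GAM couple is mass-neutral by construction
  net <- mono["atp", "mass"] + mono["h2o", "mass"] -
    mono["adp", "mass"] - mono["pi", "mass"]
  expect_lt(abs(net), 1e-9)
})

test_that("composition assembly closes to 1 g/g under both policies", {
  meas <- c(soluble_protein = 0.406, lipid = 0.084, carbohydrate = 0.021,
            rna = 0.226, dna = 0.022)
  comp <- assembleComposition(meas)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_equal(comp[["protein"]], 0.528, tolerance = 1e-12)
  expect_equal(comp[["peptidoglycan"]], 0.086, tolerance = 1e-12)
  expect_equal(comp[["cofactor_pool"]],
               1 - (0.528 + 0.084 + 0.021 + 0.226 + 0.022 + 0.086),
               tolerance = 1e-12)

  ## single-fraction passthrough with no additions
  solo <- assembleComposition(c(carbohydrate = 1),
                              insoluble_increment = 0, peptidoglycan = 0)
  expect_equal(solo[["carbohydrate"]], 1)
  expect_equal(solo[["cofactor_pool"]], 0)

  ## fractions beyond 1 are an error under the remainder policy
  expect_error(
    assembleComposition(c(soluble_protein = 0.9, rna = 0.15),
                        insoluble_increment = 0, peptidoglycan = 0),
    "> 1")
  ## ... but close under proportional renormalization
  prop <- assembleComposition(c(soluble_protein = 0.9, rna = 0.15),
                              insoluble_increment = 0, peptidoglycan = 0,
                              policy = "proportional")
  expect_equal(sum(prop), 1, tolerance = 1e-12)
})

test_that("protein coefficients follow the closed-form normalization", {
  ## 100 mol% glycine at fraction 0.5705: 0.5705*1000/57.052 mmol/g
  co <- proteinCoefficients(c(gly = 100), 0.5705, mono)
  expect_equal(co[["gly"]], 0.5705 * 1000 / mono["gly", "mass"],
               tolerance = 1e-12)
  expect_equal(co[["gly"]], 10.0, tolerance = 1e-3)

  ## measured profile with reference fill-in: mass-weighted sum = fraction
  aa <- fillAminoAcidProfile(putidaAminoAcidProfile())
  expect_equal(sum(aa), 100, tolerance = 1e-6)
  co2 <- proteinCoefficients(aa, 0.528, mono)
  expect_equal(sum(co2 * mono[names(co2), "mass"]) / 1000, 0.528,
               tolerance = 1e-9)

  expect_length(proteinCoefficients(aa, 0), 0)
})

test_that("amino-acid fill-in is idempotent and preserves measured ratios", {
  prof <- putidaAminoAcidProfile()
  once <- fillAminoAcidProfile(prof)
  twice <- fillAminoAcidProfile(once)
  expect_equal(unclass(once)[sort(names(once))],
               unclass(twice)[sort(names(twice))], tolerance = 1e-12)
  expect_setequal(attr(once, "filled_in"), c("cys", "met", "trp"))
  ## measured relative ratios are unchanged by renormalization
  expect_equal(once[["ala"]] / once[["gly"]], 12 / 10, tolerance = 1e-12)
})

test_that("nucleic-acid coefficients respect base pairing and mass", {
  eq <- nucleicAcidCoefficients("dna", 0.022, dnaBaseComposition(gc = 0.5),
                                mono)
  expect_equal(eq[["damp"]], eq[["dtmp"]], tolerance = 1e-12)
  expect_equal(eq[["dgmp"]], eq[["dcmp"]], tolerance = 1e-12)
  expect_equal(eq[["damp"]], eq[["dgmp"]], tolerance = 1e-12)  # gc = 0.5
  expect_equal(sum(eq * mono[names(eq), "mass"]) / 1000, 0.022,
               tolerance = 1e-9)
  ## genome-parameter route at the organism's GC content
  gc615 <- nucleicAcidCoefficients("dna", 0.022, monomers = mono)
  expect_equal(sum(gc615 * mono[names(gc615), "mass"]) / 1000, 0.022,
               tolerance = 1e-9)
  expect_length(nucleicAcidCoefficients("rna", 0, monomers = mono), 0)
  expect_error(
    nucleicAcidCoefficients("rna", 0.2, c(amp = 0.5, cmp = 0.4, gmp = 0.2,
                                          ump = 0.2), mono),
    "sum to 1")
})

test_that("DNA base composition can be computed from a genome FASTA", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", "ACGTGCGC"), fa)  # 6 GC of 8 -> gc 0.75
  bc <- dnaBaseComposition(fasta = fa)
  expect_equal(bc[["dgmp"]] + bc[["dcmp"]], 0.75, tolerance = 1e-12)
  expect_equal(sum(bc), 1, tolerance = 1e-12)
})

test_that("lipid coefficients split head groups, acyls and LPS correctly", {
  ## single head group, single acyl: one species in closed form
  co <- lipidCoefficients(0.05, head_groups = c(pe_bb = 1),
                          fatty_acids = c(acyl_160 = 1), lps_share = 0,
                          monomers = mono)
  species_mass <- mono["pe_bb", "mass"] + 2 * mono["acyl_160", "mass"]
  expect_equal(co[["pe_bb"]], 0.05 * 1000 / species_mass, tolerance = 1e-12)
  expect_equal(co[["acyl_160"]], 2 * co[["pe_bb"]], tolerance = 1e-12)

  ## head groups at the measured percentages: cardiolipin below PE
  co2 <- lipidCoefficients(0.084, lps_share = 0.034, monomers = mono)
  expect_lt(co2[["clpn_bb"]], co2[["pe_bb"]])
  expect_equal(sum(co2 * mono[names(co2), "mass"]) / 1000, 0.084,
               tolerance = 1e-9)

  ## all-LPS lipid fraction leaves no phospholipids
  co3 <- lipidCoefficients(0.05, lps_share = 0.05, monomers = mono)
  expect_identical(names(co3), "lps")
  expect_error(lipidCoefficients(0.05, lps_share = 0.06, monomers = mono),
               "lps_share")
})

test_that("finalized equations make exactly 1 g and carry the GAM couple", {
  eq <- buildPutidaBiomass(gam = 85)
  expect_equal(biomassMass(eq), 1, tolerance = 1e-6)
  expect_equal(eq@consumed[["atp"]], 85, tolerance = 1e-12)
  expect_equal(eq@produced[["adp"]], 85, tolerance = 1e-12)
  expect_true(all(eq@consumed >= 0) && all(eq@produced >= 0))

  ## deliberately doubled coefficients fail the mass check
  aa <- fillAminoAcidProfile(putidaAminoAcidProfile())
  good <- proteinCoefficients(aa, 1.0, mono)
  expect_equal(biomassMass(finalizeEquation(list(good), 0, mono)), 1,
               tolerance = 1e-9)
  expect_error(finalizeEquation(list(2 * good), gam = 0, monomers = mono),
               "mass check")
})

test_that("macromolecule coefficients scale linearly with their fraction", {
  aa <- fillAminoAcidProfile(putidaAminoAcidProfile())
  a <- proteinCoefficients(aa, 0.2, mono)
  b <- proteinCoefficients(aa, 0.4, mono)
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("elemental composition matches formula arithmetic", {
  ## glycogen-only biomass: C6H10O5 residue
  eq <- finalizeEquation(list(c(glycogen = 1000 / mono["glycogen", "mass"])),
                         gam = 0, monomers = mono)
  el <- elementalComposition(eq)
  expect_equal(el[["C"]], 6 * 12.011 / mono["glycogen", "mass"] * 100,
               tolerance = 1e-9)
  expect_equal(el[["C"]], 44.4, tolerance = 0.1)
  expect_equal(el[["H"]], 6.2, tolerance = 0.1)
  expect_equal(el[["O"]], 49.3, tolerance = 0.1)

  ## pure-glycine protein: N = 14.007/57.052
  eq2 <- finalizeEquation(list(c(gly = 1000 / mono["gly", "mass"])),
                          gam = 0, monomers = mono)
  expect_equal(elementalComposition(eq2)[["N"]], 14.007 / 57.052 * 100,
               tolerance = 1e-6)

  ## GAM exclusion: composition is invariant to the GAM term
  full0 <- elementalComposition(buildPutidaBiomass(gam = 0))
  full85 <- elementalComposition(buildPutidaBiomass(gam = 85))
  expect_equal(full0, full85, tolerance = 1e-9)
})

test_that("elemental fractions are invariant to splitting a species", {
  ## two glycogen pseudo-entries at half coefficient each == one entry
  half <- 1000 / mono["glycogen", "mass"] / 2
  eq1 <- finalizeEquation(list(c(glycogen = 2 * half)), 0, mono)
  eq2 <- finalizeEquation(list(c(glycogen = half), c(glycogen = half)),
                          0, mono)
  expect_equal(elementalComposition(eq1), elementalComposition(eq2),
               tolerance = 1e-12)
})

test_that("input tables mirror the published layout", {
  comp <- readCompositionTable(system.file("extdata",
                                           "composition_kt2440.tsv",
                                           package = "fluxrecon"))
  expect_equal(comp[["soluble_protein"]], 0.528, tolerance = 1e-12)
  aa <- readAminoAcidTable(system.file("extdata", "aa_kt2440.tsv",
                                       package = "fluxrecon"))
  expect_equal(aa[["ala"]], 12)
  expect_equal(aa[["asp"]], 5)  # Asx split equally
  expect_false("cys" %in% names(aa))
  ## table-driven assembly reproduces the built-in profile
  expect_equal(sort(names(fillAminoAcidProfile(aa))),
               sort(names(fillAminoAcidProfile(putidaAminoAcidProfile()))))
})
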