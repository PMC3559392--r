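# models for adjustment arithmetic: single compartment, all coefficients
# explicit so the concentration sums can be evaluated by hand
adjModel <- function(stoich) {
  sp <- unique(stoich$species_id)
  species <- data.frame(id = sp, compound = sub("\\[.\\]$", "", sp),
                        compartment = "c", stringsAsFactors = FALSE)
  reactions <- data.frame(id = unique(stoich$reaction_id),
                          class = "internal", lb = 0, ub = 1000,
                          objective = 0, stringsAsFactors = FALSE)
  reactions$class[1L] <- "biomass"   # silence the no-exchange warning path
  suppressWarnings(stoichiometricModel(species, reactions, stoich))
}

test_that("millimolar adjustment matches the closed form", {
  cfg <- adjustmentConfig()
  RT <- 1.987e-3 * 298

  # balanced molecularity: the two ln(0.001) terms cancel exactly
  m1 <- adjModel(data.frame(species_id = c("A[c]", "B[c]"),
                            reaction_id = "r", coefficient = c(-1, 1)))
  expect_identical(adjustToMillimolar(m1, "r", -7.25, cfg), -7.25)

  # A -> 2B: net +1 molecule, hand evaluation of the closed form
  m2 <- adjModel(data.frame(species_id = c("A[c]", "B[c]"),
                            reaction_id = "r", coefficient = c(-1, 2)))
  expect_equal(adjustToMillimolar(m2, "r", 10, cfg),
               10 + RT * log(0.001), tolerance = 1e-12)

  # H2 as a reactant uses its saturation concentration 3.4e-5
  m3 <- adjModel(data.frame(species_id = c("h2[c]", "B[c]"),
                            reaction_id = "r", coefficient = c(-1, 1)))
  expect_equal(adjustToMillimolar(m3, "r", 0, cfg),
               0 + RT * (-log(3.4e-5) + log(0.001)), tolerance = 1e-12)

  # water contributes no concentration term at all
  m4 <- adjModel(data.frame(species_id = c("A[c]", "B[c]", "h2o[c]"),
                            reaction_id = "r", coefficient = c(-1, 1, 1)))
  expect_identical(adjustToMillimolar(m4, "r", 3.5, cfg), 3.5)

  expect_error(adjustToMillimolar(m1, "r", NaN), "finite")
  expect_error(concentrationCorrections(m1, cfg, "nope"), "unknown reaction")
})

test_that("adjustment is linear in the input and scales with stoichiometry", {
  cfg <- adjustmentConfig()
  m <- adjModel(data.frame(species_id = c("A[c]", "B[c]", "C[c]"),
                           reaction_id = "r", coefficient = c(-2, 1, 2)))
  base <- adjustToMillimolar(m, "r", 0, cfg)
  for (x in c(-3, 1.5, 100))
    expect_equal(adjustToMillimolar(m, "r", x, cfg), base + x,
                 tolerance = 1e-12)
  # doubling every coefficient doubles the correction term
  m2 <- adjModel(data.frame(species_id = c("A[c]", "B[c]", "C[c]"),
                            reaction_id = "r", coefficient = c(-4, 2, 4)))
  expect_equal(adjustToMillimolar(m2, "r", 0, cfg), 2 * base,
               tolerance = 1e-12)
})

test_that("configuration validity is enforced", {
  expect_error(adjustmentConfig(T = -1), "T must be")
  expect_error(adjustmentConfig(special_conc = c(h2 = -1)),
               "strictly positive")
})

test_that("energy tables load with unknown flags and duplicate handling", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tvalue", "a\t-10.5", "b\tNA", "c\t3"), f)
  frag <- loadEnergyTable(f, "formation")
  expect_equal(sum(frag$known), 2L)
  expect_equal(sum(!frag$known), 1L)
  expect_true(is.na(frag$value[frag$id == "b"]))

  writeLines(c("id\tvalue", "a\t1", "a\t2"), f)
  expect_warning(frag2 <- loadEnergyTable(f, "formation"), "duplicate")
  expect_equal(frag2$value, 2)
  expect_error(loadEnergyTable(f, "formation", strict = TRUE), "duplicate")

  writeLines("id\tvalue", f)
  expect_warning(empty <- loadEnergyTable(f, "formation"), "empty")
  expect_equal(nrow(empty), 0L)

  # reaction tables carry the optional additive offset column
  writeLines(c("id\tvalue\toffset", "r1\t-5\t2", "r2\t1\t"), f)
  rfrag <- loadEnergyTable(f, "reaction")
  expect_equal(rfrag$offset, c(2, 0))
})

test_that("tables align to the model and flag unmatched ids", {
  m <- exampleToyModel()
  expect_warning(
    tb <- energyTables(m, formation = data.frame(id = c("A", "zz"),
                                                 value = c(-1, 2))),
    "not in the model")
  expect_error(
    energyTables(m, formation = data.frame(id = "zz", value = 2),
                 strict = TRUE),
    "not in the model")
  fm <- formationEnergies(tb)
  expect_equal(fm$known, c(TRUE, FALSE))
  expect_equal(fm$provenance, c("input", NA_character_))
  expect_s4_class(tb, "EnergyTables")
  expect_equal(energyUnit(tb), "kcal/mol")
})

test_that("offsets enter the millimolar column, not the standard one", {
  toy <- balanceToy()
  tb <- reactionEnergies(toy$tables)
  # balanced 1:1 stoichiometry everywhere except the exchanges
  expect_equal(tb$dGm[tb$reaction == "R1"], -3)
  RT <- 1.987e-3 * 298
  expect_equal(tb$dGm[tb$reaction == "EX_A(e)"], 10 - RT * log(0.001),
               tolerance = 1e-12)
})
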