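test_that("the uptake-limited chain reaches its bound exactly", {
  m <- exampleToyModel()
  f <- solveFBA(m)
  expect_equal(solverStatus(f), "optimal")
  expect_equal(objectiveValue(f), 10)
  v <- fluxes(f)
  expect_lte(max(abs(as.numeric(stoichMatrix(m) %*% v))), 1e-9)
  b <- bounds(m)
  expect_true(all(v >= b$lb - 1e-9 & v <= b$ub + 1e-9))
})

test_that("optima agree with the vertex-enumeration oracle on small LPs", {
  m <- exampleToyModel()
  b <- bounds(m)
  expect_equal(objectiveValue(solveFBA(m)),
               lpVertexOracle(stoichMatrix(m), unname(objectiveCoefficients(m)),
                              b$lb, b$ub))

  # 3-reaction / 2-metabolite LP with a reversible middle step
  species <- data.frame(id = c("X[c]", "Y[c]"), compound = c("X", "Y"),
                        compartment = "c", stringsAsFactors = FALSE)
  reactions <- data.frame(id = c("EX_X(e)", "r", "EX_Y(e)"),
                          class = c("exchange", "internal", "exchange"),
                          lb = c(-4, -1000, 0), ub = c(0, 1000, 7),
                          objective = c(0, 0, 1), stringsAsFactors = FALSE)
  stoich <- data.frame(species_id = c("X[c]", "X[c]", "Y[c]", "Y[c]"),
                       reaction_id = c("EX_X(e)", "r", "r", "EX_Y(e)"),
                       coefficient = c(-1, -1, 1, -1),
                       stringsAsFactors = FALSE)
  m2 <- stoichiometricModel(species, reactions, stoich)
  f2 <- solveFBA(fluxProblem(m2, objective = c("EX_Y(e)" = 1)))
  expect_equal(objectiveValue(f2),
               lpVertexOracle(stoichMatrix(m2), c(0, 0, 1),
                              reactions$lb, reactions$ub))
  expect_equal(objectiveValue(f2), 4)

  # randomized small models: solver optimum equals the oracle optimum
  for (seed in c(5, 23)) {
    gen <- generateSyntheticModel(syntheticSpec(
      n_compounds = 6, n_internal_reactions = 2, n_exchange_reactions = 2,
      frac_unknown_compounds = 0, seed = seed))
    b <- bounds(gen$model)
    got <- objectiveValue(solveFBA(gen$model))
    want <- lpVertexOracle(stoichMatrix(gen$model),
                           unname(objectiveCoefficients(gen$model)),
                           b$lb, b$ub)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("infeasible problems report status without fabricating fluxes", {
  # forced consumption of a species nothing produces
  species <- data.frame(id = "Z[c]", compound = "Z", compartment = "c",
                        stringsAsFactors = FALSE)
  reactions <- data.frame(id = c("sink", "obj"), class = "internal",
                          lb = c(5, 0), ub = c(10, 1), objective = c(0, 1),
                          stringsAsFactors = FALSE)
  stoich <- data.frame(species_id = "Z[c]", reaction_id = "sink",
                       coefficient = -1, stringsAsFactors = FALSE)
  m <- suppressWarnings(stoichiometricModel(species, reactions, stoich))
  f <- solveFBA(fluxProblem(m, objective = c(obj = 1)))
  expect_equal(solverStatus(f), "infeasible")
  expect_length(fluxes(f), 0L)
})

test_that("media application closes, widens and validates exchanges", {
  m <- exampleToyModel()
  p <- fluxProblem(m)
  # closing the only uptake starves the objective
  starved <- applyMedia(p, data.frame(reaction_id = "EX_A(e)", lb = 0,
                                      ub = 0))
  expect_equal(objectiveValue(solveFBA(starved)), 0)
  # widening an uptake bound cannot decrease the optimum
  wide <- applyMedia(p, data.frame(reaction_id = "EX_A(e)", lb = -20,
                                   ub = 0))
  expect_gte(objectiveValue(solveFBA(wide)), 10)
  # strict-minimal mode closes unlisted uptakes
  toy <- balanceToy()
  p2 <- applyMedia(fluxProblem(toy$model, objective = c(R1 = 1)),
                   data.frame(reaction_id = "EX_B(e)", lb = 0, ub = 1000))
  expect_equal(objectiveValue(solveFBA(p2)), 0)   # EX_A uptake closed

  expect_error(applyMedia(p, data.frame(reaction_id = "nope", lb = 0,
                                        ub = 0)), "nope")
  expect_error(applyMedia(p, data.frame(reaction_id = "v1", lb = 0,
                                        ub = 1)), "must be exchange")
})

test_that("optimum scales linearly with the bounds and re-runs identically", {
  gen <- generateSyntheticModel(syntheticSpec(seed = 4))
  m <- gen$model
  f1 <- solveFBA(m)
  f2 <- solveFBA(m)
  expect_identical(fluxes(f1), fluxes(f2))         # deterministic solver

  k <- 2.5
  mk <- m
  mk@reactions$lb <- m@reactions$lb * k
  mk@reactions$ub <- m@reactions$ub * k
  expect_equal(objectiveValue(solveFBA(mk)), k * objectiveValue(f1),
               tolerance = 1e-9)
})

test_that("the parsimonious step keeps the optimum and reduces total flux", {
  gen <- generateSyntheticModel(syntheticSpec(seed = 8))
  plain <- solveFBA(gen$model)
  pf <- solveFBA(fluxProblem(gen$model), pfba = TRUE)
  expect_equal(objectiveValue(pf), objectiveValue(plain), tolerance = 1e-9)
  expect_lte(sum(abs(fluxes(pf))), sum(abs(fluxes(plain))) + 1e-6)
  expect_lte(max(abs(as.numeric(stoichMatrix(gen$model) %*% fluxes(pf)))),
             1e-8)
})

test_that("flux problems validate their objective and bounds", {
  m <- exampleToyModel()
  expect_error(fluxProblem(m, objective = c(nope = 1)), "not in model")
  m0 <- m
  m0@reactions$objective <- 0
  m0@reactions$class[m0@reactions$class == "biomass"] <- "internal"
  expect_error(fluxProblem(m0), "no nonzero")
})
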