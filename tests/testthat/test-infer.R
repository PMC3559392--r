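# chain model A -> B -> C with per-compound energies; species ids carry a
# [c] suffix, plus an optional periplasmic copy of B to exercise the
# transfer matrix column structure
chainModel <- function(with_periplasm = FALSE) {
  species <- data.frame(
    id = c("A[c]", "B[c]", "C[c]", if (with_periplasm) "B[p]"),
    compound = c("A", "B", "C", if (with_periplasm) "B"),
    compartment = c("c", "c", "c", if (with_periplasm) "p"),
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("rAB", "rBC", if (with_periplasm) "rBt"),
    class = "internal", lb = 0, ub = 1000, objective = 0,
    stringsAsFactors = FALSE)
  stoich <- data.frame(
    species_id = c("A[c]", "B[c]", "B[c]", "C[c]",
                   if (with_periplasm) c("B[c]", "B[p]")),
    reaction_id = c("rAB", "rAB", "rBC", "rBC",
                    if (with_periplasm) c("rBt", "rBt")),
    coefficient = c(-1, 1, -1, 1, if (with_periplasm) c(-1, 1)),
    stringsAsFactors = FALSE)
  suppressWarnings(stoichiometricModel(species, reactions, stoich))
}

test_that("transfer matrix places one entry per compartmental instance", {
  m <- chainModel(with_periplasm = TRUE)
  tb <- energyTables(m, formation = data.frame(id = c("A", "C"),
                                               value = c(0, -25)))
  tm <- buildTransferMatrix(m, tb)
  expect_equal(tm$X_ids, "B")
  expect_equal(dim(tm$T_mat), c(4L, 1L))
  expect_equal(sum(tm$T_mat), 2)                      # B[c] and B[p]
  expect_true(all(Matrix::rowSums(tm$T_mat) <= 1))

  tb_all <- energyTables(m, formation = data.frame(id = c("A", "B", "C"),
                                                   value = c(0, 1, 2)))
  expect_warning(tm0 <- buildTransferMatrix(m, tb_all), "no-op")
  expect_equal(ncol(tm0$T_mat), 0L)
})

test_that("the reduced system selects known-energy rows touching unknowns", {
  m <- chainModel()
  tb <- energyTables(m,
    formation = data.frame(id = c("A", "C"), value = c(0, -25)),
    reaction = data.frame(id = "rAB", value = -10))
  sys <- buildInferenceSystem(m, tb)
  expect_equal(sys$usable_rows, "rAB")
  expect_equal(unname(sys$Q), matrix(1))
  expect_equal(sys$b, -10)

  # a known-energy reaction touching no unknown compound is excluded
  tb2 <- energyTables(m,
    formation = data.frame(id = "B", value = -10),   # A, C unknown
    reaction = data.frame(id = "rAB", value = -10))
  sys2 <- buildInferenceSystem(m, tb2)
  expect_equal(sys2$usable_rows, "rAB")
  expect_equal(colnames(sys2$Q), c("A", "C"))

  # unknowns with zero usable rows are named in the error
  tb3 <- energyTables(m, formation = data.frame(id = "B", value = -10))
  expect_error(buildInferenceSystem(m, tb3), "underdetermined")
})

test_that("least squares matches pseudo-inverse and normal-equations oracles", {
  sol <- solveLeastSquares(matrix(1), -10)
  expect_equal(unname(sol$X0), -10)
  expect_equal(sol$residuals, 0)
  expect_equal(sol$rank, 1L)

  # consistent overdetermined system: two rows pin one unknown
  Q <- matrix(c(1, 2), ncol = 1); b <- c(5, 10)
  sol2 <- solveLeastSquares(Q, b)
  expect_equal(unname(sol2$X0), solve(crossprod(Q), crossprod(Q, b))[1L])
  expect_equal(sol2$residuals, c(0, 0), tolerance = 1e-12)

  # random small systems against MASS::ginv, including rank-deficient ones
  set.seed(71)
  for (k in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(1:6, 1)
    Q <- matrix(rnorm(nr * nc), nr, nc)
    if (k %% 3 == 0 && nc > 1) Q[, nc] <- Q[, 1L]     # force deficiency
    b <- rnorm(nr)
    sol <- solveLeastSquares(Q, b)
    expect_equal(unname(sol$X0), pinvOracle(Q, b), tolerance = 1e-8)
  }

  expect_error(solveLeastSquares(matrix(NA_real_), 1), "non-finite")
})

test_that("rank-deficient solutions have minimum norm along the solution line", {
  # two unknowns appearing only as a sum: x1 + x2 = 4
  Q <- matrix(c(1, 1), nrow = 1)
  sol <- solveLeastSquares(Q, 4)
  # 1-D grid search over the line (t, 4 - t)
  ts <- seq(-10, 10, by = 0.001)
  norms <- ts^2 + (4 - ts)^2
  t_best <- ts[which.min(norms)]
  expect_equal(unname(sol$X0), c(t_best, 4 - t_best), tolerance = 1e-6)
  expect_equal(sol$rank, 1L)
  expect_true(all(sol$weakly_determined))
})

test_that("back-substitution completes the tables without overwriting input", {
  m <- chainModel()
  tb <- energyTables(m,
    formation = data.frame(id = c("A", "C"), value = c(0, -25)),
    reaction = data.frame(id = "rAB", value = -10))
  res <- completeEnergies(m, tb)
  rx <- reactionEnergies(res$tables)
  # hand-computed two-step chain: dGf(B) = -10, so rBC = -25 - (-10) = -15
  expect_equal(rx$dGr0[rx$reaction == "rBC"], -15)
  expect_equal(rx$provenance[rx$reaction == "rBC"], "inferred")
  expect_equal(rx$dGr0[rx$reaction == "rAB"], -10)     # untouched input
  expect_equal(rx$provenance[rx$reaction == "rAB"], "input")
  fm <- formationEnergies(res$tables)
  expect_equal(fm$value[fm$compound == "B"], -10)
  expect_equal(fm$provenance[fm$compound == "B"], "inferred")

  # idempotence: completed tables have no unknowns and re-running keeps
  # every value (the transfer matrix degenerates to zero columns)
  expect_warning(res2 <- completeEnergies(m, res$tables), "no-op")
  expect_equal(reactionEnergies(res2$tables)$dGr0, rx$dGr0)
  expect_equal(formationEnergies(res2$tables)$value, fm$value)
})

test_that("all-known tables give a no-op completion consistent with Eq-style conservation", {
  gen <- generateSyntheticModel(syntheticSpec(frac_unknown_compounds = 0,
                                              seed = 3))
  expect_warning(res <- completeEnergies(gen$model, gen$masked), "no-op")
  rx <- reactionEnergies(res$tables)
  truth <- reactionEnergies(gen$truth)
  expect_equal(rx$dGr0, truth$dGr0, tolerance = 1e-10)
  # conservation: F0 reproduces sum s_i * dGf_i for every reaction
  expect_equal(unname(res$F0), truth$dGr0, tolerance = 1e-10)
})

test_that("noise-free synthetic models are recovered and reported consistent", {
  gen <- generateSyntheticModel(syntheticSpec(seed = 11))
  res <- completeEnergies(gen$model, gen$masked)
  fm <- formationEnergies(res$tables)
  got <- fm$value[match(gen$masked_compounds, fm$compound)]
  want <- gen$dGf_true[gen$masked_compounds]
  expect_lt(max(abs(got - want) / abs(want)), 1e-6)
  verdicts <- res$report$verdict
  expect_equal(verdicts[1L], "cannot compare")
  expect_true(all(verdicts[-1L] == "consistent"))
  expect_lt(max(res$report$max_discrepancy, na.rm = TRUE), 1e-8)
})

test_that("noise enters category 2 but never category 3", {
  base <- syntheticSpec(seed = 19)
  rms2 <- sapply(c(0.5, 1, 2), function(sd) {
    gen <- generateSyntheticModel(syntheticSpec(seed = 19, noise_sd = sd))
    res <- completeEnergies(gen$model, gen$masked)
    expect_equal(res$report$max_discrepancy[3L], 0)   # category 3 exact
    res$report$rms_discrepancy[2L]
  })
  expect_true(all(diff(rms2) > 0))                    # grows with sigma
})
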