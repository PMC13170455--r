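test_that("FBA solves simple networks to their hand-computed optima", {
  chain <- chainModel(uptake = 10)
  sol <- fba(chain)
  expect_identical(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 10)
  ## objective clamped to zero
  clamped <- setBounds(chain, "EX_c", lower = 0, upper = 0)
  expect_equal(objectiveValue(fba(clamped)), 0)
  ## anaerobic glycolysis: 2 ATP per glucose at uptake 10
  expect_equal(atpCapacity(glycolysisFixture(10)), 20)
})

test_that("optimal flux vectors satisfy mass balance and bounds", {
  for (model in list(chainModel(), diamondModel(), glycolysisFixture(),
                     applyMedium(buildToyNetwork(), defaultMedium()))) {
    sol <- fba(model)
    v <- fluxes(sol)
    S <- as.matrix(stoichiometricMatrix(model))
    expect_lt(max(abs(S %*% v)), 1e-6)
    expect_true(all(v >= lowerBounds(model) - 1e-9))
    expect_true(all(v <= upperBounds(model) + 1e-9))
  }
})

test_that("FVA brackets fluxes correctly on small networks", {
  dia <- diamondModel(uptake = 5)
  ## throughput pinned at 5: interchangeable branches each span [0, 5]
  pinned <- setBounds(dia, "EX_p", lower = 5)
  rng <- fluxRanges(fva(pinned, fractionOfOptimum = 0))
  expect_equal(unname(rng["r1", ]), c(0, 5), tolerance = 1e-8)
  expect_equal(unname(rng["r2", ]), c(0, 5), tolerance = 1e-8)
  ## fraction 1 on a linear chain: the solution is unique, all ranges collapse
  rngC <- fluxRanges(fva(chainModel(), fractionOfOptimum = 1))
  expect_true(all(abs(rngC[, "max"] - rngC[, "min"]) < 1e-8))
  ## FVA range of the objective at fraction 1 equals the FBA optimum
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  opt <- objectiveValue(fba(toy))
  rngT <- fluxRanges(fva(toy, fractionOfOptimum = 1,
                         reactions = "BIOMASS"))
  expect_equal(unname(rngT["BIOMASS", "min"]), opt, tolerance = 1e-6)
  expect_equal(unname(rngT["BIOMASS", "max"]), opt, tolerance = 1e-6)
})

test_that("FVA matches a brute-force per-reaction oracle", {
  for (model in list(chainModel(), diamondModel(), pppFixture(),
                     glycolysisFixture())) {
    rng <- fluxRanges(fva(model, fractionOfOptimum = 0))
    want <- bruteRange(model, objectiveMin = 0)
    expect_equal(unname(rng[, "min"]), unname(want[, "min"]),
                 tolerance = 1e-6)
    expect_equal(unname(rng[, "max"]), unname(want[, "max"]),
                 tolerance = 1e-6)
  }
})

test_that("production capacity probes work and leave the model untouched", {
  ppp <- pppFixture(glucose = 10)
  ## 2 NADPH per glucose-6-phosphate at glucose uptake 10
  expect_equal(productionCapacity(ppp, "nadph_c"), 20)
  before <- ppp
  productionCapacity(ppp, "nadph_c")
  expect_identical(modelHash(ppp), modelHash(before))
  ## repeated calls agree
  expect_equal(productionCapacity(ppp, "nadph_c"),
               productionCapacity(ppp, "nadph_c"))
  ## blocking the only producing reaction zeroes the capacity
  blocked <- setBounds(ppp, "G6PD", lower = 0, upper = 0)
  expect_equal(productionCapacity(blocked, "nadph_c"), 0)
  expect_error(productionCapacity(ppp, "nope_c"), "not in model")
})

test_that("secretion capacity respects stoichiometric limits", {
  gly <- glycolysisFixture(10)
  ## fully fermentative: 2 lactate per glucose
  expect_equal(secretionCapacity(gly, "EX_lac"), 20)
  blocked <- setBounds(gly, "GLYC", lower = 0, upper = 0)
  expect_equal(secretionCapacity(blocked, "EX_lac"), 0)
  expect_error(secretionCapacity(gly, "GLYC"), "not an exchange")
})

test_that("adding constraints never increases a maximised objective", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  base <- objectiveValue(fba(toy))
  for (spec in defaultInhibitorPanel()) {
    pm <- applyBlock(toy, spec)
    expect_lte(objectiveValue(fba(pm)), base + 1e-9)
  }
  ## medium tightening
  med <- defaultMedium(); med["EX_glc"] <- 2
  expect_lte(objectiveValue(fba(applyMedium(toy, med))), base + 1e-9)
})
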