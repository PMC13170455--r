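test_that("the toy network is valid, consistent and elementally balanced", {
  toy <- buildToyNetwork()
  expect_true(validObject(toy))
  ## authored consistent: the consistency pass is the identity
  expect_length(findBlockedReactions(toy), 0)
  ## every internal reaction balances carbon and oxygen exactly
  bal <- elementalBalance(toy, c("C", "O"))
  expect_lt(max(abs(bal)), 1e-9)
  ## nitrogen and phosphorus balance too (the pool formulas are authored)
  balNP <- elementalBalance(toy, c("N", "P"))
  expect_lt(max(abs(balNP)), 1e-9)
})

test_that("default medium reproduces the frozen reference capacities", {
  manifest <- jsonlite::fromJSON(system.file("extdata", "toy_manifest.json",
                                             package = "TcellFlux"))
  m <- applyMedium(buildToyNetwork(), defaultMedium())
  expect_equal(objectiveValue(fba(m)), manifest$biomass_default_medium,
               tolerance = 1e-8)
  expect_equal(atpCapacity(m), manifest$atp_capacity_default_medium,
               tolerance = 1e-8)
  expect_equal(nadphCapacity(m), manifest$nadph_capacity_default_medium,
               tolerance = 1e-8)
  expect_equal(secretionCapacity(m, "EX_lac"),
               manifest$lactate_capacity_default_medium, tolerance = 1e-8)
  expect_true(all(defaultMedium() >= 0))
})

test_that("expression simulation is deterministic and noise-controlled", {
  spec <- archetypeSpec("ebv_like", seed = 4L)
  r1 <- simulateExpression(spec)
  r2 <- simulateExpression(archetypeSpec("ebv_like", seed = 4L))
  expect_equal(lapply(r1, expressionValues), lapply(r2, expressionValues))
  ## zero noise: replicates identical and equal to baseline x multiplier
  quiet <- archetypeSpec("hd_like", noiseCv = 0, seed = 1L)
  q <- simulateExpression(quiet)
  expect_equal(expressionValues(q[[1]]), expressionValues(q[[2]]))
  expect_equal(expressionValues(q[[1]]),
               quiet$baseline * quiet$multipliers)
  ## unexpressed genes are absent from the profiles
  tab <- archetypeMultipliers()
  off <- tab$gene[tab$hd_like == 0]
  expect_false(any(off %in% names(expressionValues(q[[1]]))))
})

test_that("replicate means recover baseline times multiplier within noise", {
  spec <- archetypeSpec("alps_like", noiseCv = 0.1, seed = 11L)
  m <- meanExpression(simulateExpression(spec, nReplicates = 3L))
  mu <- spec$baseline * spec$multipliers
  rel <- expressionValues(m)[names(mu)] / mu
  ## lognormal with cv 0.1, mean of 3: deviations beyond ~3 sd are not
  ## expected (sd of the mean about 6%)
  expect_true(all(abs(rel - 1) < 0.2))
})

test_that("dropping glutamine from the medium starves the activated archetype", {
  res <- archetypeResults()
  ctx <- res$alps_like$model
  med <- defaultMedium()
  med <- med[names(med) != "EX_gln"]
  starved <- applyMedium(setBounds(ctx, "EX_gln", lower = 0), med)
  expect_lt(objectiveValue(fba(starved)), 1e-6)
})
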