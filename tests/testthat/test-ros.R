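test_that("superoxide coupling rewrites stoichiometry conservatively", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  ## fraction 0: stoichiometry untouched except for the inert leak sink
  c0 <- addSuperoxideCoupling(toy, fraction = 0)
  expect_identical(c0$challenge@etcReactionIds, "ETC")
  S0 <- as.matrix(stoichiometricMatrix(c0$model))
  St <- as.matrix(stoichiometricMatrix(toy))
  expect_equal(S0[rownames(St), colnames(St)], St)
  expect_true(c0$challenge@leakSinkId %in% reactions(c0$model)$id)

  ## fraction f diverts f * |O2 coefficient| per unit flux to superoxide
  c2 <- addSuperoxideCoupling(toy, fraction = 0.02)
  S2 <- as.matrix(stoichiometricMatrix(c2$model))
  expect_equal(S2["o2s_m", "ETC"], 0.02 * 0.5)
  ## ...so an ETC flux of 10 produces 0.1 mmol superoxide
  expect_equal(10 * S2["o2s_m", "ETC"], 0.1)
  ## oxygen atoms conserved: product water shrinks by twice the diversion
  expect_equal(S2["h2o_m", "ETC"], St["h2o_m", "ETC"] - 2 * 0.02 * 0.5)
  ## full elemental check on the rewritten reaction
  bal <- elementalBalance(c2$model, c("C", "O"))
  expect_lt(max(abs(bal)), 1e-9)
  expect_error(addSuperoxideCoupling(toy, fraction = 2), "fraction")
})

test_that("blocked detox routes force all superoxide through the leak sink", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  ch <- addSuperoxideCoupling(toy, fraction = 0.1)
  m <- ch$model
  detox <- intersect(c("SODm", "SODc", "ASCBSOX", "GSHSOX", "O2St"),
                     reactions(m)$id)
  m <- setBounds(m, detox, lower = 0, upper = 0)
  ## with detox blocked, max ETC flux is leak-capacity / (f * |O2 coeff|)
  m2 <- setBounds(m, ch$challenge@leakSinkId, upper = 2)
  sol <- fba(m2, objective = "ETC")
  expect_equal(objectiveValue(sol), 2 / (0.1 * 0.5), tolerance = 1e-6)
})

test_that("increasing the superoxide fraction never increases max biomass", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  vals <- vapply(c(0, 0.02, 0.1, 0.5), function(f)
    objectiveValue(fba(addSuperoxideCoupling(toy, f)$model)), 0)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("superoxide fate balances per sample and matches the model hash", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  ch <- addSuperoxideCoupling(toy, fraction = 0.02)
  smp <- sampleFluxes(ch$model, n = 300, seed = 5, warmup = 200,
                      thinning = 2)
  fate <- superoxideFate(ch$model, ch$challenge, smp)
  expect_lt(fate$maxResidual, 1e-6)
  per <- fate$perSample
  expect_equal(per[, "production"],
               per[, "sod_total"] + per[, "ascorbate_detox"] +
                 per[, "glutathione_path"] + per[, "leakage"],
               tolerance = 1e-6)
  expect_true(all(per >= -1e-9))
  ## samples from another model are rejected
  other <- sampleFluxes(chainModel(), n = 10, seed = 1, warmup = 10,
                        thinning = 1)
  expect_error(superoxideFate(ch$model, ch$challenge, other), "hash")
})

test_that("fraction zero yields all-zero fate components", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  ## close the basal NADPH-oxidase superoxide source so the only possible
  ## producer is the (inactive) challenge
  toy <- setBounds(toy, "NOX", lower = 0, upper = 0)
  ch <- addSuperoxideCoupling(toy, fraction = 0)
  smp <- sampleFluxes(ch$model, n = 100, seed = 5, warmup = 100,
                      thinning = 2)
  fate <- superoxideFate(ch$model, ch$challenge, smp)
  expect_lt(max(abs(fate$perSample)), 1e-6)
})

test_that("NADPH capacity reflects the PPP and its inhibition", {
  ppp <- pppFixture(glucose = 10)
  expect_equal(nadphCapacity(ppp), 20)
  expect_equal(nadphCapacity(setBounds(ppp, "G6PD", lower = 0, upper = 0)), 0)
  ## opening an additional NADPH source never lowers the capacity
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  base <- nadphCapacity(toy)
  narrowed <- setBounds(toy, "G6PD", upper = 1)
  expect_lte(nadphCapacity(narrowed), base + 1e-9)
})
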