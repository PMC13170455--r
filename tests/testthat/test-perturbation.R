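test_that("blocking fixes bounds at zero and is idempotent", {
  chain <- chainModel()
  once <- applyBlock(chain, "TA")
  twice <- applyBlock(once, "TA")
  expect_identical(reactions(once), reactions(twice))
  expect_equal(unname(upperBounds(once)["TA"]), 0)
  ## blocking the only precursor uptake kills the objective
  expect_equal(objectiveValue(fba(applyBlock(chain, "EX_a"))), 0)
  ## a parallel branch keeps throughput unchanged
  dia <- diamondModel()
  expect_equal(objectiveValue(fba(applyBlock(dia, "r2"))),
               objectiveValue(fba(dia)))
  expect_error(applyBlock(chain, "nope"), "unknown reaction")
})

test_that("gene-level specs resolve through GPR membership", {
  toy <- buildToyNetwork()
  hits <- resolvePerturbation(toy, PerturbationSpec("hex", genes = "HK1"))
  expect_identical(hits, "HEX1")
  ## G6PD gene hits the complex-rule reaction
  expect_identical(
    resolvePerturbation(toy, PerturbationSpec("ppp", genes = "G6PD")),
    "G6PD")
  ## ids absent from a context model resolve to nothing
  expect_length(
    resolvePerturbation(chainModel(),
                        PerturbationSpec("hex", genes = "HK1")), 0)
})

test_that("anoxia closes oxygen uptake only, found by metabolite identity", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  anox <- anoxia(toy)
  expect_equal(unname(lowerBounds(anox)["EX_o2"]), 0)
  expect_equal(unname(upperBounds(anox)["EX_o2"]),
               unname(upperBounds(toy)["EX_o2"]))
  ## ATP capacity falls to the substrate-level value: full oxidation yields
  ## more ATP than fermentation in the authored network
  expect_lt(atpCapacity(anox), atpCapacity(toy))
  ## biomass persists anaerobically (fermentation covers the ATP demand)
  expect_gt(objectiveValue(fba(anox)), 0)
  ## already-anaerobic model unchanged
  expect_identical(reactions(anoxia(anox)), reactions(anox))
  expect_error(anoxia(chainModel()), "no extracellular O2")
})

test_that("inhibitor panel reports relatives against one shared baseline", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  panel <- defaultInhibitorPanel()
  res <- inhibitorPanel(toy, panel, objective = "biomass")
  expect_identical(res$label,
                   vapply(panel, function(p) p@label, "",
                          USE.NAMES = FALSE))
  expect_true(all(res$baseline == res$baseline[1]))
  expect_true(all(res$relative <= 1 + 1e-9))
  expect_true(all(res$relative >= -1e-9))
  ## failure flag is equivalent to a (near-)zero optimum
  expect_identical(res$failed, res$perturbed < 1e-6)
  ## an empty effective block reports relative exactly 1
  noop <- inhibitorPanel(toy, list(PerturbationSpec("x", genes = "NOGENE")),
                         objective = "biomass")
  expect_equal(noop$relative, 1)
  expect_identical(noop$n_blocked, 0L)
})

test_that("panel results are independent of spec order", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  panel <- defaultInhibitorPanel()
  fwd <- inhibitorPanel(toy, panel, objective = "atp")
  rev <- inhibitorPanel(toy, rev(panel), objective = "atp")
  rev <- rev[match(fwd$label, rev$label), ]
  rownames(rev) <- NULL; rownames(fwd) <- NULL
  expect_equal(fwd, rev)
})
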