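test_that("replicate averaging uses the union of genes with absent-as-zero", {
  p1 <- ExpressionProfile(c(g1 = 1, g2 = 3), label = "x")
  p2 <- ExpressionProfile(c(g1 = 2, g2 = 3), label = "x")
  p3 <- ExpressionProfile(c(g1 = 3), label = "x")
  m <- meanExpression(list(p1, p2, p3))
  expect_equal(expressionValues(m)[["g1"]], 2)
  ## g2 present in 2 of 3 replicates as (3, 3): mean 2 under absent-as-zero
  expect_equal(expressionValues(m)[["g2"]], 2)
  expect_identical(m@nReplicates, 3L)
  ## a single replicate comes back unchanged
  single <- meanExpression(list(p1))
  expect_equal(expressionValues(single), expressionValues(p1))
  expect_error(meanExpression(list()), "no replicates")
})

test_that("reaction scores follow GPR rules and flag missing associations", {
  toy <- buildToyNetwork()
  vals <- stats::setNames(rep(1, length(genes(toy))), genes(toy))
  vals["HK1"] <- 5; vals["G6PD"] <- 4; vals["PGD"] <- 2
  sc <- gprScore(toy, ExpressionProfile(vals, label = "t"))
  expect_equal(unname(sc["HEX1"]), 5)
  expect_equal(unname(sc["G6PD"]), 2)      # AND rule takes the minimum
  expect_true(is.na(sc["ATPM"]))           # no GPR -> missing
  expect_true(is.na(sc["BIOMASS"]))
})

test_that("core selection applies the quantile rule over scored reactions", {
  toy <- buildToyNetwork()
  mand <- mandatoryCore()
  ## synthetic scores: 8 scored reactions valued 1..8
  scored <- reactions(toy)$id[nzchar(reactions(toy)$gpr)][1:8]
  sc <- stats::setNames(rep(NA_real_, nrow(reactions(toy))),
                        reactions(toy)$id)
  sc[scored] <- 1:8
  core <- selectCore(toy, sc, 0.75, mand)
  ## sort-based oracle: type-7 interpolation at rank 1 + 0.75 * 7
  s <- sort(1:8); h <- 1 + 0.75 * 7
  thr <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  wanted <- scored[(1:8) >= thr]
  expect_setequal(coreReactions(core),
                  union(coreReactions(mand), wanted))
  ## mandatory reactions enter even with score zero or missing
  expect_true(all(coreReactions(mand) %in% coreReactions(core)))
  ## equal scores with >= comparison keep every scored reaction
  sc[scored] <- 3
  coreEq <- selectCore(toy, sc, 0.75, mand)
  expect_true(all(scored %in% coreReactions(coreEq)))
  expect_error(selectCore(toy, sc, 1.5, mand), "thresholdQuantile")
})

test_that("eFlux scales bounds proportionally to expression", {
  toy <- buildToyNetwork()
  vals <- stats::setNames(rep(5, length(genes(toy))), genes(toy))
  vals["MDH1"] <- 10                        # top score, reversible NADHT
  vals["HK1"] <- 5
  sc <- gprScore(toy, ExpressionProfile(vals, label = "t"))
  scaled <- efluxBounds(toy, sc, vMax = 1000)
  ## top-scored reversible reaction spans the full +/- vMax
  expect_equal(unname(lowerBounds(scaled)["NADHT"]), -1000)
  expect_equal(unname(upperBounds(scaled)["NADHT"]), 1000)
  ## half the top score gives half the bound; irreversible floor at 0
  expect_equal(unname(upperBounds(scaled)["HEX1"]), 500)
  expect_equal(unname(lowerBounds(scaled)["HEX1"]), 0)
  ## reactions without GPR and exchanges keep their bounds
  expect_equal(unname(upperBounds(scaled)["ATPM"]), 1000)
  expect_equal(unname(lowerBounds(scaled)["EX_glc"]), -1000)
})

test_that("uniform scores reproduce the unscaled optimum and only ratios matter", {
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  vals <- stats::setNames(rep(7, length(genes(toy))), genes(toy))
  sc <- gprScore(toy, ExpressionProfile(vals, label = "t"))
  uniform <- efluxBounds(toy, sc, vMax = 1000)
  ## uniform expression: every scaled bound is vMax, so the optimum matches
  ## the unscaled model's (its internal bounds are also 1000)
  expect_equal(objectiveValue(fba(uniform)), objectiveValue(fba(toy)),
               tolerance = 1e-8)
  ## scaling the whole profile leaves eFlux bounds unchanged
  sc2 <- gprScore(toy, ExpressionProfile(vals * 13, label = "t"))
  expect_equal(reactions(efluxBounds(toy, sc2, 1000)),
               reactions(uniform))
})

test_that("raising one gene's expression never lowers any eFlux bound", {
  toy <- buildToyNetwork()
  base <- stats::setNames(runif(length(genes(toy)), 1, 10), genes(toy))
  set.seed(3)
  for (g in sample(genes(toy), 5)) {
    lo <- gprScore(toy, ExpressionProfile(base, label = "t"))
    hi <- base; hi[g] <- hi[g] * 2
    ## only meaningful when the bumped gene is not the maximum already
    hiSc <- gprScore(toy, ExpressionProfile(hi, label = "t"))
    if (max(hiSc, na.rm = TRUE) > max(lo, na.rm = TRUE)) next
    mLo <- efluxBounds(toy, lo, 1000)
    mHi <- efluxBounds(toy, hiSc, 1000)
    expect_true(all(upperBounds(mHi) >= upperBounds(mLo) - 1e-9))
  }
})

test_that("expression profiles round-trip through TSV", {
  p <- ExpressionProfile(c(gA = 1.5, gB = 0), label = "ct")
  path <- tempfile(fileext = ".tsv")
  writeExpressionProfile(p, path)
  back <- readExpressionProfile(path, label = "ct")
  expect_equal(expressionValues(back), expressionValues(p))
})
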