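test_that("blocked reactions are exactly the dead ends", {
  ## chain with EX_c closed: both internal reactions are blocked
  closedEnd <- setBounds(chainModel(), "EX_c", lower = 0, upper = 0)
  expect_setequal(findBlockedReactions(closedEnd),
                  c("EX_a", "TA", "TB", "EX_c"))
  ## fully open chain: nothing blocked
  expect_length(findBlockedReactions(chainModel()), 0)
  ## dangling branch: only the dead-end reaction is blocked
  expect_identical(findBlockedReactions(deadEndModel()), "DEAD")
  ## cut PPP exit: the PPP reactions become blocked, verified independently
  ppp <- setBounds(pppFixture(), "EX_ru5p", lower = 0, upper = 0)
  blocked <- findBlockedReactions(ppp)
  lp <- jsonStoich(ppp)
  wantBlocked <- lp$ids[vapply(seq_along(lp$ids), function(j) {
    obj <- numeric(length(lp$ids)); obj[j] <- 1
    mx <- bruteLP(obj, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub, TRUE)$objval
    mn <- bruteLP(obj, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub, FALSE)$objval
    mx < 1e-4 && mn > -1e-4
  }, TRUE)]
  expect_setequal(blocked, wantBlocked)
})

test_that("tightening bounds never shrinks the blocked set", {
  base <- deadEndModel()
  b0 <- findBlockedReactions(base)
  tightened <- setBounds(base, "EX_a", lower = 0)
  b1 <- findBlockedReactions(tightened)
  expect_true(all(b0 %in% b1))
})

test_that("fastcc extracts the largest consistent sub-model", {
  ## a consistent model is a fixed point
  toy <- buildToyNetwork()
  expect_identical(sort(reactions(fastcc(toy))$id),
                   sort(reactions(toy)$id))
  ## one dead-end reaction removed, the rest intact
  cc <- fastcc(deadEndModel())
  expect_setequal(reactions(cc)$id, c("EX_a", "TA", "TB", "EX_c"))
  expect_false("d_c" %in% metabolites(cc)$id)
  ## output equals the complement of the blocked set
  ppp <- setBounds(pppFixture(), "EX_ru5p", lower = 0, upper = 0)
  expect_setequal(reactions(fastcc(ppp))$id,
                  setdiff(reactions(ppp)$id, findBlockedReactions(ppp)))
})

test_that("fastcore returns a minimal consistent sub-network containing the core", {
  ## unique pathway: the middle reaction pulls in the whole chain
  chain <- chainModel()
  got <- fastcore(CoreSet("TA"), chain)
  expect_setequal(reactions(got)$id, c("EX_a", "TA", "TB", "EX_c"))
  ## core = everything is the identity
  all <- fastcore(CoreSet(reactions(chain)$id), chain)
  expect_setequal(reactions(all)$id, reactions(chain)$id)
  ## diamond: core r1 must include r1 and exclude the parallel branch
  dia <- diamondModel()
  sub <- fastcore(CoreSet("r1"), dia)
  expect_true("r1" %in% reactions(sub)$id)
  expect_false("r2" %in% reactions(sub)$id)
  ## a core reaction missing from the model is an error
  expect_error(fastcore(CoreSet("nope"), chain), "not in model")
})

test_that("fastcore output is consistent and exactly minimal on small fixtures", {
  fixtures <- list(list(model = diamondModel(), core = "r1"),
                   list(model = deadEndModel(), core = "TB"),
                   list(model = chainModel(), core = "TB"))
  for (fx in fixtures) {
    model <- fastcc(fx$model)
    got <- fastcore(CoreSet(fx$core), model)
    ids <- reactions(got)$id
    expect_true(all(fx$core %in% ids))
    expect_true(all(ids %in% reactions(model)$id))
    ## re-running the consistency pass is the identity
    expect_setequal(reactions(fastcc(got))$id, ids)
    ## exhaustive enumeration: no smaller consistent superset of the core
    others <- setdiff(reactions(model)$id, fx$core)
    minimal <- length(reactions(model)$id)
    for (mask in 0:(2^length(others) - 1)) {
      pick <- others[as.logical(bitwAnd(bitwShiftR(mask,
                       seq_along(others) - 1L), 1L))]
      subset <- c(fx$core, pick)
      if (length(subset) < minimal &&
          subsetConsistent(model, subset)) minimal <- length(subset)
    }
    expect_identical(length(ids), minimal)
  }
})

test_that("two-cycle report flags opposing duplicate reactions", {
  mets <- data.frame(id = c("a_e", "b_c"), compartment = c("e", "c"))
  m <- MetabolicModel(mets, list(
    list(id = "EX_a", stoichiometry = c(a_e = -1),
         lower_bound = -10, upper_bound = 10),
    list(id = "F", stoichiometry = c(a_e = -1, b_c = 1),
         lower_bound = 0, upper_bound = 10),
    list(id = "Rv", stoichiometry = c(a_e = 1, b_c = -1),
         lower_bound = 0, upper_bound = 10)
  ), objective = "EX_a")
  cyc <- findTwoCycles(m)
  expect_identical(nrow(cyc), 1L)
  expect_setequal(unlist(cyc[1, ]), c("F", "Rv"))
  expect_identical(nrow(findTwoCycles(chainModel())), 0L)
})
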