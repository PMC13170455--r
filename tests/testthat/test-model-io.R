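test_that("models round-trip through JSON and SBML unchanged", {
  toy <- buildToyNetwork()
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = paste0(".", fmt))
    writeMetabolicModel(toy, path, format = fmt)
    back <- readMetabolicModel(path, format = fmt)
    expect_equal(metabolites(back)$id, metabolites(toy)$id)
    expect_equal(metabolites(back)$compartment, metabolites(toy)$compartment)
    expect_equal(metabolites(back)$formula, metabolites(toy)$formula)
    expect_equal(reactions(back)$id, reactions(toy)$id)
    expect_equal(reactions(back)$lower_bound, reactions(toy)$lower_bound)
    expect_equal(reactions(back)$upper_bound, reactions(toy)$upper_bound)
    expect_equal(reactions(back)$subsystem, reactions(toy)$subsystem)
    expect_equal(objectiveReaction(back), objectiveReaction(toy))
    expect_setequal(genes(back), genes(toy))
    expect_equal(as.matrix(stoichiometricMatrix(back)),
                 as.matrix(stoichiometricMatrix(toy)))
    ## GPR semantics preserved (string layout may differ)
    vals <- stats::setNames(seq_along(genes(toy)), genes(toy))
    expect_equal(
      vapply(reactions(back)$gpr, evalGPR, 0, values = vals,
             USE.NAMES = FALSE),
      vapply(reactions(toy)$gpr, evalGPR, 0, values = vals,
             USE.NAMES = FALSE))
  }
})

test_that("writing the same model twice is byte-identical", {
  toy <- buildToyNetwork()
  for (fmt in c("json", "sbml")) {
    p1 <- tempfile(fileext = paste0(".", fmt))
    p2 <- tempfile(fileext = paste0(".", fmt))
    writeMetabolicModel(toy, p1, format = fmt)
    writeMetabolicModel(toy, p2, format = fmt)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("truncated or malformed files raise parse errors, not partial models", {
  toy <- chainModel()
  path <- tempfile(fileext = ".xml")
  writeMetabolicModel(toy, path, format = "sbml")
  txt <- readChar(path, file.size(path))
  cut <- tempfile(fileext = ".xml")
  writeChar(substr(txt, 1, nchar(txt) %/% 2), cut, eos = NULL)
  expect_error(readMetabolicModel(cut, format = "sbml"))
  expect_error(readMetabolicModel(tempfile(), format = "json"), "not found")
})

test_that("toy fixture matches its frozen manifest", {
  manifest <- jsonlite::fromJSON(system.file("extdata", "toy_manifest.json",
                                             package = "TcellFlux"))
  toy <- buildToyNetwork()
  expect_identical(nrow(metabolites(toy)), manifest$n_metabolites)
  expect_identical(nrow(reactions(toy)), manifest$n_reactions)
  expect_identical(length(genes(toy)), manifest$n_genes)
  expect_identical(length(exchangeReactions(toy)), manifest$n_exchanges)
  expect_identical(sort(unique(metabolites(toy)$compartment)),
                   manifest$compartments)
})

test_that("stoichiometric matrix entries match reaction definitions", {
  chain <- chainModel()
  S <- as.matrix(stoichiometricMatrix(chain))
  expect_identical(dim(S), c(3L, 4L))
  expect_equal(unname(S[, "TA"]), c(-1, 1, 0))
  expect_equal(unname(S[, "TB"]), c(0, -1, 1))
  ## rebuilding reactions from the matrix reproduces every stoichiometry
  toy <- buildToyNetwork()
  St <- stoichiometricMatrix(toy)
  expect_identical(dim(St), c(nrow(metabolites(toy)),
                              nrow(reactions(toy))))
  lp <- jsonStoich(toy)          # independently reassembled matrix
  expect_equal(as.matrix(St)[rownames(lp$S), colnames(lp$S)], lp$S)
})

test_that("applyMedium closes unlisted uptakes and never widens bounds", {
  toy <- buildToyNetwork()
  med <- c(EX_glc = 10)
  m <- applyMedium(toy, med)
  expect_equal(unname(lowerBounds(m)["EX_glc"]), -10)
  expect_equal(unname(lowerBounds(m)["EX_gln"]), 0)
  ## secretion (upper) bounds untouched
  expect_equal(upperBounds(m), upperBounds(toy))
  ## no bound widened
  expect_true(all(lowerBounds(m) >= lowerBounds(toy)))
  ## empty medium: nothing can enter, biomass is zero
  closed <- applyMedium(toy, stats::setNames(numeric(), character()))
  expect_equal(objectiveValue(fba(closed)), 0, tolerance = 1e-9)
  ## full default medium supports growth
  expect_gt(objectiveValue(fba(applyMedium(toy, defaultMedium()))), 0)
  ## a non-exchange id is rejected
  expect_error(applyMedium(toy, c(HEX1 = 5)), "not exchange")
})

test_that("medium specs round-trip through TSV", {
  med <- defaultMedium()
  path <- tempfile(fileext = ".tsv")
  writeMedium(med, path)
  expect_equal(readMedium(path), med)
})

test_that("SBML output is readable by an independent SBML library", {
  ## cross-check with python-libsbml/cobrapy, which also re-solves the FBA
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  toy <- applyMedium(buildToyNetwork(), defaultMedium())
  path <- tempfile(fileext = ".xml")
  writeMetabolicModel(toy, path, format = "sbml")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "print(len(m.metabolites), len(m.reactions), len(m.genes))",
    "print(round(m.slim_optimize(), 6))"
  ), script)
  out <- system2(py, c(script, path), stdout = TRUE, stderr = FALSE)
  counts <- as.integer(strsplit(out[1], " ")[[1]])
  expect_identical(counts, c(nrow(metabolites(toy)),
                             nrow(reactions(toy)),
                             length(genes(toy))))
  expect_equal(as.numeric(out[2]), objectiveValue(fba(toy)),
               tolerance = 1e-5)
})
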