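## Shared fixtures and independent oracles.
##
## bruteLP enumerates all basic solutions (every choice of basis columns,
## every on-bound assignment of the nonbasic variables) after reducing the
## constraint rows to an independent set, and is therefore a solver-free
## oracle for any small LP. jsonStoich reassembles a model's constraint
## matrix from its JSON export, independently of the package's sparse-matrix
## path.

bruteLP <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  qd <- qr(t(A))
  keep <- qd$pivot[seq_len(qd$rank)]
  Ar <- A[keep, , drop = FALSE]
  br <- b[keep]
  m <- nrow(Ar); n <- ncol(Ar)
  best <- NULL; bestval <- if (maximize) -Inf else Inf; feasible <- FALSE
  combs <- utils::combn(n, m)
  for (k in seq_len(ncol(combs))) {
    Bi <- combs[, k]
    B <- Ar[, Bi, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    Ni <- setdiff(seq_len(n), Bi)
    ng <- length(Ni)
    for (mask in 0:(2^ng - 1)) {
      up <- as.logical(bitwAnd(bitwShiftR(mask, seq_len(ng) - 1L), 1L))
      xN <- ifelse(up, ub[Ni], lb[Ni])
      rhs <- br - if (ng) Ar[, Ni, drop = FALSE] %*% xN else 0
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[Ni] <- xN; x[Bi] <- xB
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8) &&
          max(abs(A %*% x - b)) < 1e-6) {
        feasible <- TRUE
        v <- sum(obj * x)
        if ((maximize && v > bestval) || (!maximize && v < bestval)) {
          bestval <- v; best <- x
        }
      }
    }
  }
  if (!feasible) return(list(status = "infeasible", objval = NA_real_))
  list(status = "optimal", objval = bestval, x = best)
}

## Constraint matrix rebuilt from the JSON export (independent of the
## package's Matrix-based path).
jsonStoich <- function(model) {
  path <- tempfile(fileext = ".json")
  writeMetabolicModel(model, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- vapply(doc$metabolites, function(m) m$id, "")
  rxns <- vapply(doc$reactions, function(r) r$id, "")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in doc$reactions)
    for (met in names(r$metabolites))
      S[met, r$id] <- r$metabolites[[met]]
  list(S = S,
       lb = vapply(doc$reactions, function(r) r$lower_bound, 0),
       ub = vapply(doc$reactions, function(r) r$upper_bound, 0),
       ids = rxns)
}

## Per-reaction flux range by brute force on the JSON-derived matrix.
bruteRange <- function(model, objectiveMin = NULL) {
  lp <- jsonStoich(model)
  lb <- lp$lb
  if (!is.null(objectiveMin)) {
    jo <- match(objectiveReaction(model), lp$ids)
    lb[jo] <- max(lb[jo], objectiveMin)
  }
  t(vapply(seq_along(lp$ids), function(j) {
    obj <- numeric(length(lp$ids)); obj[j] <- 1
    c(min = bruteLP(obj, lp$S, rep(0, nrow(lp$S)), lb, lp$ub, FALSE)$objval,
      max = bruteLP(obj, lp$S, rep(0, nrow(lp$S)), lb, lp$ub, TRUE)$objval)
  }, c(min = 0, max = 0)))
}

## --- small fixture networks ------------------------------------------------

## linear chain a_e -> b_c -> c_e with both exchanges open
chainModel <- function(uptake = 10) {
  mets <- data.frame(id = c("a_e", "b_c", "c_e"),
                     compartment = c("e", "c", "e"))
  MetabolicModel(mets, list(
    list(id = "EX_a", stoichiometry = c(a_e = -1),
         lower_bound = -uptake, upper_bound = 1000),
    list(id = "TA", stoichiometry = c(a_e = -1, b_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "TB", stoichiometry = c(b_c = -1, c_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_c", stoichiometry = c(c_e = -1),
         lower_bound = 0, upper_bound = 1000)
  ), objective = "EX_c")
}

## two parallel branches r1/r2 between a shared inlet and outlet
diamondModel <- function(uptake = 5) {
  mets <- data.frame(id = c("s_e", "s_c", "x_c", "p_e"),
                     compartment = c("e", "c", "c", "e"))
  MetabolicModel(mets, list(
    list(id = "EX_s", stoichiometry = c(s_e = -1),
         lower_bound = -uptake, upper_bound = 0),
    list(id = "UP", stoichiometry = c(s_e = -1, s_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "r1", stoichiometry = c(s_c = -1, x_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "r2", stoichiometry = c(s_c = -1, x_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "OUT", stoichiometry = c(x_c = -1, p_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_p", stoichiometry = c(p_e = -1),
         lower_bound = 0, upper_bound = 1000)
  ), objective = "EX_p")
}

## minimal oxidative-PPP fixture: glucose-6-phosphate dehydrogenase is the
## only NADPH source, 2 NADPH per glucose. NADP+ is importable so that a
## bare NADPH removal sink can carry flux despite the conserved pool.
pppFixture <- function(glucose = 10) {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "g6p_c", "nadp_c", "nadph_c", "ru5p_c",
           "ru5p_e", "co2_e", "co2_c", "nadp_e"),
    compartment = c("e", "c", "c", "c", "c", "c", "e", "e", "c", "e"))
  MetabolicModel(mets, list(
    list(id = "EX_nadp", stoichiometry = c(nadp_e = -1),
         lower_bound = -1000, upper_bound = 1000),
    list(id = "NADPt", stoichiometry = c(nadp_e = -1, nadp_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_glc", stoichiometry = c(glc_e = -1),
         lower_bound = -glucose, upper_bound = 0),
    list(id = "GLCt", stoichiometry = c(glc_e = -1, glc_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "HK", stoichiometry = c(glc_c = -1, g6p_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "HK1"),
    list(id = "G6PD", stoichiometry = c(g6p_c = -1, nadp_c = -2,
                                        ru5p_c = 1, co2_c = 1, nadph_c = 2),
         lower_bound = 0, upper_bound = 1000, gpr = "G6PD"),
    list(id = "RU5Pt", stoichiometry = c(ru5p_c = -1, ru5p_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_ru5p", stoichiometry = c(ru5p_e = -1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "CO2t", stoichiometry = c(co2_c = -1, co2_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_co2", stoichiometry = c(co2_e = -1),
         lower_bound = 0, upper_bound = 1000)
  ), objective = "EX_ru5p")
}

## anaerobic glycolysis fixture: 2 ATP per glucose, ATP demand objective
glycolysisFixture <- function(glucose = 10) {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "lac_c", "lac_e", "atp_c", "adp_c"),
    compartment = c("e", "c", "c", "e", "c", "c"))
  MetabolicModel(mets, list(
    list(id = "EX_glc", stoichiometry = c(glc_e = -1),
         lower_bound = -glucose, upper_bound = 0),
    list(id = "GLCt", stoichiometry = c(glc_e = -1, glc_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "GLYC", stoichiometry = c(glc_c = -1, adp_c = -2,
                                        lac_c = 2, atp_c = 2),
         lower_bound = 0, upper_bound = 1000, gpr = "PKM"),
    list(id = "LACt", stoichiometry = c(lac_c = -1, lac_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_lac", stoichiometry = c(lac_e = -1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "ATPM", stoichiometry = c(atp_c = -1, adp_c = 1),
         lower_bound = 0, upper_bound = 1000)
  ), objective = "ATPM")
}

## chain with a dangling dead-end branch (d_c has no outlet)
deadEndModel <- function() {
  mets <- data.frame(id = c("a_e", "b_c", "c_e", "d_c"),
                     compartment = c("e", "c", "e", "c"))
  MetabolicModel(mets, list(
    list(id = "EX_a", stoichiometry = c(a_e = -1),
         lower_bound = -10, upper_bound = 1000),
    list(id = "TA", stoichiometry = c(a_e = -1, b_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "TB", stoichiometry = c(b_c = -1, c_e = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "DEAD", stoichiometry = c(b_c = -1, d_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "EX_c", stoichiometry = c(c_e = -1),
         lower_bound = 0, upper_bound = 1000)
  ), objective = "EX_c")
}

## exhaustive flux-consistency check of a reaction subset, by brute force
subsetConsistent <- function(model, keepIds, epsilon = 1e-4) {
  keep <- match(keepIds, reactions(model)$id)
  lp <- jsonStoich(model)
  S <- lp$S[, keep, drop = FALSE]
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  lb <- lp$lb[keep]; ub <- lp$ub[keep]
  for (j in seq_along(keep)) {
    obj <- numeric(length(keep)); obj[j] <- 1
    mx <- bruteLP(obj, S, rep(0, nrow(S)), lb, ub, TRUE)
    mn <- bruteLP(obj, S, rep(0, nrow(S)), lb, ub, FALSE)
    if (mx$status != "optimal") return(FALSE)
    if (mx$objval < epsilon && mn$objval > -epsilon) return(FALSE)
  }
  TRUE
}

## shared small pipeline run for the acceptance-pattern tests (computed once)
archetypeResults <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- runConfig(seed = 7L, samplingN = 1500L, samplingWarmup = 300L,
                       samplingThinning = 4L)
      cache <<- runPipeline(cfg)
    }
    cache
  }
})
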