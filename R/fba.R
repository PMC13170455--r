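## Flux balance analysis and derived capacity analyses. All of these are thin
## LP formulations over the shared steady-state system S v = 0, lb <= v <= ub.

.lpData <- function(model) {
  list(S = as.matrix(model@stoichiometry),
       lb = model@reactions$lower_bound,
       ub = model@reactions$upper_bound,
       ids = model@reactions$id)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction subject to steady-state
#' mass balance \eqn{S v = 0} and the flux bounds, and reports the optimal
#' flux distribution.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective objective reaction id; defaults to the model objective
#'   (the biomass reaction).
#' @param sense \code{"max"} or \code{"min"}.
#' @return A \linkS4class{FluxSolution}.
#' @export
fba <- function(model, objective = objectiveReaction(model),
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  lp <- .lpData(model)
  j <- match(objective, lp$ids)
  if (is.na(j)) stop("objective reaction not in model: ", objective)
  obj <- numeric(length(lp$ids)); obj[j] <- 1
  res <- solveLP(obj, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub,
                 maximize = sense == "max")
  if (res$status != "optimal") {
    return(new("FluxSolution",
               fluxes = stats::setNames(rep(NA_real_, length(lp$ids)), lp$ids),
               objectiveValue = NA_real_, status = res$status))
  }
  new("FluxSolution", fluxes = stats::setNames(res$x, lp$ids),
      objectiveValue = res$objval, status = "optimal")
}

#' Flux variability analysis
#'
#' Computes, for each requested reaction, the minimum and maximum flux
#' attainable while the objective reaction retains at least
#' \code{fractionOfOptimum} of its FBA optimum ("at optimal biomass" for the
#' default fraction of 1).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param fractionOfOptimum number in [0, 1].
#' @param reactions reaction ids to analyse (default all).
#' @return A \linkS4class{FluxRange}.
#' @export
fva <- function(model, fractionOfOptimum = 1, reactions = NULL) {
  stopifnot(fractionOfOptimum >= 0, fractionOfOptimum <= 1)
  .fvaCore(model, fractionOfOptimum, reactions)$range
}

## Shared FVA engine. fraction = NULL drops the objective constraint entirely
## (used by the sampler, which explores the whole flux space). Returns the
## FluxRange plus the optimal flux vectors of every directional LP, which the
## sampler reuses as warmup points.
.fvaCore <- function(model, fraction = 1, reactions = NULL,
                     keepSolutions = FALSE) {
  lp <- .lpData(model)
  lb <- lp$lb; ub <- lp$ub
  if (!is.null(fraction)) {
    jo <- match(model@objective, lp$ids)
    sol <- fba(model)
    if (solverStatus(sol) != "optimal")
      stop("FVA: model is ", solverStatus(sol))
    opt <- objectiveValue(sol)
    lb[jo] <- max(lb[jo], fraction * opt)
    if (lb[jo] > ub[jo] + 1e-9) stop("FVA: objective constraint infeasible")
  }
  targets <- if (is.null(reactions)) lp$ids else reactions
  jt <- match(targets, lp$ids)
  if (anyNA(jt)) stop("unknown reaction id(s): ",
                      paste(targets[is.na(jt)], collapse = ", "))
  n <- length(lp$ids)
  rng <- matrix(NA_real_, length(jt), 2,
                dimnames = list(targets, c("min", "max")))
  sols <- if (keepSolutions)
    matrix(NA_real_, 2 * length(jt), n, dimnames = list(NULL, lp$ids)) else NULL
  b0 <- rep(0, nrow(lp$S))
  for (k in seq_along(jt)) {
    obj <- numeric(n); obj[jt[k]] <- 1
    rmin <- solveLP(obj, lp$S, b0, lb, ub, maximize = FALSE)
    rmax <- solveLP(obj, lp$S, b0, lb, ub, maximize = TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("FVA LP not optimal for reaction ", targets[k], " (",
           rmin$status, "/", rmax$status, ")")
    rng[k, ] <- c(rmin$objval, rmax$objval)
    if (keepSolutions) {
      sols[2 * k - 1, ] <- rmin$x
      sols[2 * k, ] <- rmax$x
    }
  }
  list(range = new("FluxRange", ranges = rng,
                   fractionOfOptimum = if (is.null(fraction)) 0 else fraction),
       solutions = sols, lb = lb, ub = ub)
}

#' Maximum production capacity of a metabolite
#'
#' Temporarily adds an irreversible sink reaction (1 metabolite -> nothing,
#' bounds [0, vMax]) and maximises its flux; the input model is not modified.
#' This is the standard sink-reaction probe, used e.g. for NADPH production
#' capacity.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param metabolite metabolite id to drain.
#' @param vMax sink capacity, default 1000 mmol/gDW/h.
#' @return Maximal sink flux (mmol/gDW/h).
#' @export
productionCapacity <- function(model, metabolite, vMax = 1000) {
  lp <- .lpData(model)
  i <- match(metabolite, model@metabolites$id)
  if (is.na(i)) stop("metabolite not in model: ", metabolite)
  S <- cbind(lp$S, 0)
  S[i, ncol(S)] <- -1
  obj <- c(numeric(length(lp$ids)), 1)
  res <- solveLP(obj, S, rep(0, nrow(S)), c(lp$lb, 0), c(lp$ub, vMax))
  if (res$status != "optimal")
    stop("production-capacity LP is ", res$status, " for ", metabolite)
  res$objval
}

#' Maximum ATP production capacity
#'
#' Maximal flux through the ATP demand reaction (ATP + H2O -> ADP + Pi),
#' the conventional readout for how much ATP turnover a model can sustain.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param demandId id of the ATP demand reaction, default \code{"ATPM"}.
#' @return Maximal demand flux (mmol/gDW/h).
#' @export
atpCapacity <- function(model, demandId = "ATPM") {
  if (!(demandId %in% model@reactions$id))
    stop("ATP demand reaction not in model: ", demandId)
  sol <- fba(model, objective = demandId, sense = "max")
  if (solverStatus(sol) != "optimal")
    stop("ATP-capacity LP is ", solverStatus(sol))
  objectiveValue(sol)
}

#' Maximum secretion capacity through an exchange reaction
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param exchangeId id of an exchange reaction.
#' @return Maximal (positive = secretion) exchange flux (mmol/gDW/h).
#' @export
secretionCapacity <- function(model, exchangeId) {
  if (!(exchangeId %in% exchangeReactions(model)))
    stop("not an exchange reaction: ", exchangeId)
  sol <- fba(model, objective = exchangeId, sense = "max")
  if (solverStatus(sol) != "optimal")
    stop("secretion-capacity LP is ", solverStatus(sol))
  objectiveValue(sol)
}
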