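## In silico inhibitor panel: reaction blocking, anoxia, and relative
## biomass/ATP reporting. Enzyme-level inhibitors are specified by gene: all
## reactions whose GPR mentions one of the genes are blocked, mirroring
## "blocking all reactions facilitated by" an enzyme. A per-model override is
## possible by giving explicit reaction ids in the spec.

#' Reactions targeted by a perturbation in a given model
#'
#' Resolves a \linkS4class{PerturbationSpec} against a model: explicit
#' reaction ids are intersected with the model (ids absent from a
#' context-specific model are silently dropped -- extraction legitimately
#' prunes pathways per cell type), and gene ids select every reaction whose
#' GPR references them.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param spec a \linkS4class{PerturbationSpec}.
#' @return Character vector of reaction ids (possibly empty).
#' @export
resolvePerturbation <- function(model, spec) {
  rxn <- model@reactions
  hit <- intersect(spec@reactionIds, rxn$id)
  if (length(spec@geneIds)) {
    byGene <- rxn$id[vapply(rxn$gpr, function(g)
      nzchar(g) && any(gprGenes(g) %in% spec@geneIds), TRUE)]
    hit <- union(hit, byGene)
  }
  hit
}

#' Block a set of reactions
#'
#' Returns a copy of the model with both bounds of every listed reaction set
#' to 0. Idempotent; everything else untouched.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param spec a \linkS4class{PerturbationSpec} or character vector of
#'   reaction ids.
#' @return Blocked copy of the model.
#' @export
applyBlock <- function(model, spec) {
  ids <- if (is(spec, "PerturbationSpec")) {
    explicit <- setdiff(spec@reactionIds, model@reactions$id)
    if (length(explicit))
      stop("perturbation ", sQuote(spec@label),
           " names unknown reaction(s): ", paste(explicit, collapse = ", "))
    resolvePerturbation(model, spec)
  } else {
    unknown <- setdiff(spec, model@reactions$id)
    if (length(unknown))
      stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
    spec
  }
  if (length(ids) == 0) return(model)
  setBounds(model, ids, lower = 0, upper = 0)
}

#' Simulate anoxia
#'
#' Closes the uptake direction of the oxygen exchange reaction. Oxygen is
#' located by metabolite identity (elemental formula O2 in the extracellular
#' compartment), not by reaction id, so renamed models still work; secretion
#' is unaffected.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return Anoxic copy of the model.
#' @export
anoxia <- function(model) {
  met <- model@metabolites
  isO2 <- !is.na(met$formula) & met$formula == "O2" &
    met$compartment == "e" &
    (is.na(met$charge) | met$charge == 0)
  if (!any(isO2)) stop("no extracellular O2 metabolite in model")
  o2Ids <- met$id[isO2]
  ex <- exchangeReactions(model)
  S <- model@stoichiometry
  target <- ex[vapply(ex, function(r) {
    i <- which(S[, match(r, model@reactions$id)] != 0)
    met$id[i] %in% o2Ids
  }, TRUE)]
  if (length(target) == 0) stop("no O2 exchange reaction in model")
  idx <- match(target, model@reactions$id)
  model@reactions$lower_bound[idx] <- pmax(model@reactions$lower_bound[idx], 0)
  model
}

#' Run an inhibitor panel
#'
#' Applies each perturbation to the model, recomputes the objective optimum
#' (biomass FBA or ATP demand capacity), and reports it relative to the
#' unperturbed baseline. Perturbations whose targets were pruned from the
#' model resolve to an empty block and report relative = 1. An optimum below
#' \code{feasTol} is flagged as failed ("zero biomass flux").
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param panel list of \linkS4class{PerturbationSpec}s.
#' @param objective \code{"biomass"} (model objective) or \code{"atp"}
#'   (ATP demand capacity).
#' @param atpDemandId ATP demand reaction id, default \code{"ATPM"}.
#' @param feasTol failure threshold, default 1e-6 mmol/gDW/h.
#' @return data.frame with columns \code{label}, \code{n_blocked},
#'   \code{baseline}, \code{perturbed}, \code{relative}, \code{failed}.
#' @export
inhibitorPanel <- function(model, panel, objective = c("biomass", "atp"),
                           atpDemandId = "ATPM", feasTol = 1e-6) {
  objective <- match.arg(objective)
  evalObjective <- function(m) {
    if (objective == "atp") {
      sol <- fba(m, objective = atpDemandId, sense = "max")
    } else {
      sol <- fba(m)
    }
    if (solverStatus(sol) != "optimal") return(NA_real_)
    max(objectiveValue(sol), 0)
  }
  baseline <- evalObjective(model)
  if (is.na(baseline)) stop("baseline model is infeasible")
  if (baseline < feasTol)
    stop("baseline optimum is below the feasibility threshold")
  rows <- lapply(panel, function(spec) {
    ids <- resolvePerturbation(model, spec)
    if (length(ids) == 0) {
      return(data.frame(label = spec@label, n_blocked = 0L,
                        baseline = baseline, perturbed = baseline,
                        relative = 1, failed = FALSE))
    }
    pm <- setBounds(model, ids, lower = 0, upper = 0)
    val <- evalObjective(pm)
    if (is.na(val)) val <- 0
    data.frame(label = spec@label, n_blocked = length(ids),
               baseline = baseline, perturbed = val,
               relative = min(val / baseline, 1), failed = val < feasTol)
  })
  do.call(rbind, rows)
}
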