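#' @include AllGenerics.R
NULL

#' MetabolicModel: a genome-scale metabolic network
#'
#' Container for a constraint-based metabolic model: metabolites with
#' compartments and (optional) elemental formulas, reactions with flux bounds
#' (mmol/gDW/h) and gene-protein-reaction (GPR) rules, the gene universe, and
#' a single objective reaction (by convention the biomass reaction).
#' The model defines the steady-state flux space \eqn{\{v : S v = 0,\;
#' lb \le v \le ub\}}.
#'
#' The sign convention follows SBML-FBC practice: exchange reactions are
#' written \code{1 met_e ->} (coefficient -1), so uptake is a negative
#' exchange flux and secretion a positive one.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula}, \code{charge}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound}, \code{gpr}, \code{subsystem}.
#' @slot stoichiometry sparse metabolite-by-reaction coefficient matrix.
#' @slot genes character vector of gene identifiers.
#' @slot objective id of the objective reaction.
#'
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    genes = "character",
    objective = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- validateModelInternal(object)
  if (length(msgs) == 0) TRUE else msgs
})

## Returns a character vector of problems (empty when valid). Shared by the
## validity method (strict) and readMetabolicModel(strict = FALSE).
validateModelInternal <- function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (any(!nzchar(met$compartment)))
    msgs <- c(msgs, "metabolites with empty compartment")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "stoichiometry dimensions do not match metabolites/reactions")
  if (any(rxn$lower_bound > rxn$upper_bound + 1e-12))
    msgs <- c(msgs, sprintf("lower_bound > upper_bound for: %s",
                            paste(rxn$id[rxn$lower_bound > rxn$upper_bound + 1e-12],
                                  collapse = ", ")))
  nnz <- Matrix::colSums(S != 0)
  if (any(nnz == 0))
    msgs <- c(msgs, sprintf("reactions with empty stoichiometry: %s",
                            paste(rxn$id[nnz == 0], collapse = ", ")))
  for (i in seq_along(rxn$id)) {
    g <- rxn$gpr[i]
    if (nzchar(g)) {
      gg <- tryCatch(gprGenes(g), error = function(e) NULL)
      if (is.null(gg)) {
        msgs <- c(msgs, sprintf("unparseable GPR in reaction %s", rxn$id[i]))
      } else if (!all(gg %in% object@genes)) {
        msgs <- c(msgs, sprintf("GPR gene(s) of %s missing from gene set: %s",
                                rxn$id[i],
                                paste(setdiff(gg, object@genes), collapse = ", ")))
      }
    }
  }
  if (nrow(rxn) > 0 &&
      (length(object@objective) != 1 || !(object@objective %in% rxn$id)))
    msgs <- c(msgs, "objective does not resolve to a reaction id")
  msgs
}

#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with at least \code{id} and
#'   \code{compartment}; \code{name}, \code{formula}, \code{charge} optional.
#' @param reactions list of reaction descriptions; each element is a list with
#'   \code{id}, \code{stoichiometry} (named numeric, metabolite id to signed
#'   coefficient), \code{lower_bound}, \code{upper_bound}, and optionally
#'   \code{name}, \code{gpr}, \code{subsystem}.
#' @param objective id of the objective reaction.
#' @param genes gene universe; defaults to the union of all GPR genes.
#'
#' @return A validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(metabolites, reactions, objective,
                           genes = NULL) {
  met <- data.frame(
    id = as.character(metabolites$id),
    name = if (!is.null(metabolites$name)) as.character(metabolites$name)
           else as.character(metabolites$id),
    compartment = as.character(metabolites$compartment),
    formula = if (!is.null(metabolites$formula)) as.character(metabolites$formula)
              else NA_character_,
    charge = if (!is.null(metabolites$charge)) as.integer(metabolites$charge)
             else NA_integer_,
    stringsAsFactors = FALSE
  )
  rids <- vapply(reactions, function(r) r$id, "")
  rxn <- data.frame(
    id = rids,
    name = vapply(reactions, function(r) if (is.null(r$name)) r$id else r$name, ""),
    lower_bound = vapply(reactions, function(r) as.numeric(r$lower_bound), 0),
    upper_bound = vapply(reactions, function(r) as.numeric(r$upper_bound), 0),
    gpr = vapply(reactions, function(r) if (is.null(r$gpr)) "" else r$gpr, ""),
    subsystem = vapply(reactions, function(r)
      if (is.null(r$subsystem)) "" else r$subsystem, ""),
    stringsAsFactors = FALSE
  )
  triplets <- do.call(rbind, lapply(seq_along(reactions), function(j) {
    st <- reactions[[j]]$stoichiometry
    st <- st[st != 0]
    if (length(st) == 0) stop("reaction ", rids[j], " has empty stoichiometry")
    idx <- match(names(st), met$id)
    if (anyNA(idx))
      stop("reaction ", rids[j], " references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    cbind(i = idx, j = j, x = as.numeric(st))
  }))
  S <- Matrix::sparseMatrix(i = triplets[, "i"], j = triplets[, "j"],
                            x = triplets[, "x"],
                            dims = c(nrow(met), nrow(rxn)),
                            dimnames = list(met$id, rxn$id))
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(rxn$gpr[nzchar(rxn$gpr)], gprGenes))))
    if (is.null(genes)) genes <- character()
  }
  new("MetabolicModel", metabolites = met, reactions = rxn,
      stoichiometry = S, genes = as.character(genes),
      objective = as.character(objective))
}

#' @describeIn MetabolicModel metabolite table accessor
#' @param object,x a MetabolicModel
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @describeIn MetabolicModel reaction table accessor
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @describeIn MetabolicModel gene universe accessor
#' @export
setMethod("genes", "MetabolicModel", function(object) object@genes)

#' @describeIn MetabolicModel objective reaction id
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(object) object@objective)

#' @describeIn MetabolicModel set the objective reaction
#' @param value new objective reaction id
#' @export
setMethod("objectiveReaction<-", "MetabolicModel", function(object, value) {
  stopifnot(value %in% object@reactions$id)
  object@objective <- value
  object
})

#' @describeIn MetabolicModel named lower-bound vector
#' @export
setMethod("lowerBounds", "MetabolicModel", function(object)
  stats::setNames(object@reactions$lower_bound, object@reactions$id))

#' @describeIn MetabolicModel named upper-bound vector
#' @export
setMethod("upperBounds", "MetabolicModel", function(object)
  stats::setNames(object@reactions$upper_bound, object@reactions$id))

#' @describeIn MetabolicModel return a copy with bounds replaced for the given
#'   reaction ids (NULL leaves the respective bound untouched)
#' @param ids reaction ids
#' @param lower,upper replacement bounds, recycled to \code{length(ids)}
#' @export
setMethod("setBounds", "MetabolicModel", function(object, ids, lower = NULL,
                                                  upper = NULL) {
  idx <- match(ids, object@reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  if (!is.null(lower)) object@reactions$lower_bound[idx] <- rep_len(lower, length(idx))
  if (!is.null(upper)) object@reactions$upper_bound[idx] <- rep_len(upper, length(idx))
  validObject(object)
  object
})

#' @describeIn MetabolicModel the sparse stoichiometric matrix S (metabolites
#'   by reactions); entry (i, j) is the coefficient of metabolite i in
#'   reaction j
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel", function(object)
  object@stoichiometry)

#' @describeIn MetabolicModel ids of exchange reactions: reactions touching
#'   exactly one metabolite, which lives in the extracellular compartment
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object) {
  S <- object@stoichiometry
  nnz <- Matrix::colSums(S != 0)
  single <- which(nnz == 1)
  extra <- object@metabolites$id[object@metabolites$compartment == "e"]
  keep <- vapply(single, function(j) {
    i <- which(S[, j] != 0)
    object@metabolites$id[i] %in% extra
  }, TRUE)
  object@reactions$id[single[keep]]
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      length(object@genes), "genes\n")
  cat("  compartments:",
      paste(sort(unique(object@metabolites$compartment)), collapse = ", "), "\n")
  cat("  objective:", object@objective, "\n")
})

## ---------------------------------------------------------------------------

#' FluxSolution: result of one flux balance analysis
#'
#' @slot fluxes named flux vector (mmol/gDW/h); NA when not optimal.
#' @slot objectiveValue optimal objective; NA when not optimal.
#' @slot status "optimal", "infeasible" or "unbounded".
#' @export
setClass("FluxSolution",
  representation(fluxes = "numeric", objectiveValue = "numeric",
                 status = "character"))

#' @describeIn FluxSolution named flux vector
#' @param object a FluxSolution
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)
#' @describeIn FluxSolution optimal objective value
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)
#' @describeIn FluxSolution solver status string
#' @export
setMethod("solverStatus", "FluxSolution", function(object) object@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status)
  if (object@status == "optimal")
    cat(", objective =", format(object@objectiveValue, digits = 6))
  cat("\n")
})

#' FluxRange: flux variability analysis result
#'
#' @slot ranges two-column matrix (min, max) with reaction-id rownames.
#' @slot fractionOfOptimum objective retention used for the FVA constraint.
#' @export
setClass("FluxRange",
  representation(ranges = "matrix", fractionOfOptimum = "numeric"))

#' @describeIn FluxRange min/max matrix accessor
#' @param object a FluxRange
#' @export
setMethod("fluxRanges", "FluxRange", function(object) object@ranges)

setMethod("show", "FluxRange", function(object) {
  cat("FluxRange:", nrow(object@ranges), "reactions at fraction",
      object@fractionOfOptimum, "of optimum\n")
})

#' FluxSampleSet: steady-state flux samples
#'
#' Rows are samples, columns reactions. Metadata records the seed, the
#' sampling algorithm, warmup and thinning, and a hash of the sampled model so
#' that downstream summaries can verify provenance.
#'
#' @slot samples n-by-reactions numeric matrix (mmol/gDW/h).
#' @slot reactionIndex ordered reaction ids (column names).
#' @slot seed,warmup,thinning sampler settings.
#' @slot algorithm sampler name.
#' @slot modelHash hash of the model the samples were drawn from.
#' @export
setClass("FluxSampleSet",
  representation(samples = "matrix", reactionIndex = "character",
                 seed = "integer", algorithm = "character",
                 warmup = "integer", thinning = "integer",
                 modelHash = "character"))

#' @describeIn FluxSampleSet sample matrix accessor
#' @param object a FluxSampleSet
#' @export
setMethod("samples", "FluxSampleSet", function(object) object@samples)

setMethod("show", "FluxSampleSet", function(object) {
  cat("FluxSampleSet:", nrow(object@samples), "samples x",
      ncol(object@samples), "reactions (", object@algorithm,
      ", seed", object@seed, ")\n")
})

#' ExpressionProfile: gene expression for one cell type
#'
#' @slot values named non-negative expression vector (gene id to value).
#' @slot label cell-type label.
#' @slot nReplicates number of biological replicates averaged into the values.
#' @export
setClass("ExpressionProfile",
  representation(values = "numeric", label = "character",
                 nReplicates = "integer"))

setValidity("ExpressionProfile", function(object) {
  if (length(object@values) == 0) return("values must be non-empty")
  if (is.null(names(object@values)) || any(!nzchar(names(object@values))))
    return("values must be named by gene id")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("values must be finite and >= 0")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  TRUE
})

#' @rdname ExpressionProfile-class
#' @param values named non-negative numeric vector
#' @param label cell-type label
#' @param nReplicates replicate count
#' @export
ExpressionProfile <- function(values, label = "", nReplicates = 1L) {
  new("ExpressionProfile", values = values, label = as.character(label),
      nReplicates = as.integer(nReplicates))
}

#' Expression values of a profile
#' @param profile an \linkS4class{ExpressionProfile}
#' @return named numeric vector
#' @export
expressionValues <- function(profile) profile@values

#' Cell-type label of a profile
#' @param profile an \linkS4class{ExpressionProfile}
#' @export
expressionLabel <- function(profile) profile@label

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile:", length(object@values), "genes, label =",
      sQuote(object@label), ", replicates =", object@nReplicates, "\n")
})

#' CoreSet: reactions that a context-specific model must retain
#'
#' @slot reactionIds reaction ids forming the core.
#' @slot epsilon minimum activation flux (mmol/gDW/h) used by the
#'   consistency/extraction algorithms.
#' @export
setClass("CoreSet",
  representation(reactionIds = "character", epsilon = "numeric"))

setValidity("CoreSet", function(object) {
  if (length(object@reactionIds) == 0) return("core set must be non-empty")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  TRUE
})

#' @rdname CoreSet-class
#' @param reactionIds character vector of reaction ids
#' @param epsilon minimum activation flux, default 1e-4 mmol/gDW/h
#' @export
CoreSet <- function(reactionIds, epsilon = 1e-4) {
  new("CoreSet", reactionIds = unique(as.character(reactionIds)),
      epsilon = as.numeric(epsilon))
}

#' Reaction ids of a core set
#' @param core a \linkS4class{CoreSet}
#' @export
coreReactions <- function(core) core@reactionIds

setMethod("show", "CoreSet", function(object) {
  cat("CoreSet:", length(object@reactionIds), "reactions, epsilon =",
      object@epsilon, "\n")
})

#' PerturbationSpec: one in silico inhibitor
#'
#' Either a set of reaction ids to block outright, or a set of genes whose
#' GPR-associated reactions are blocked (mirroring enzyme inhibition, e.g.
#' all reactions facilitated by CPT1).
#'
#' @slot label inhibitor label.
#' @slot reactionIds reaction ids to block (possibly empty).
#' @slot geneIds gene ids whose reactions are blocked (possibly empty).
#' @export
setClass("PerturbationSpec",
  representation(label = "character", reactionIds = "character",
                 geneIds = "character"))

setValidity("PerturbationSpec", function(object) {
  if (length(object@reactionIds) == 0 && length(object@geneIds) == 0)
    return("a perturbation must name at least one reaction or gene")
  TRUE
})

#' @rdname PerturbationSpec-class
#' @param label inhibitor label
#' @param reactions reaction ids to block
#' @param genes gene ids whose GPR-associated reactions are blocked
#' @export
PerturbationSpec <- function(label, reactions = character(),
                             genes = character()) {
  new("PerturbationSpec", label = as.character(label),
      reactionIds = as.character(reactions), geneIds = as.character(genes))
}

setMethod("show", "PerturbationSpec", function(object) {
  cat("PerturbationSpec", sQuote(object@label), ":",
      length(object@reactionIds), "reaction id(s),",
      length(object@geneIds), "gene(s)\n")
})

#' SuperoxideChallenge: bookkeeping of a superoxide-production transform
#'
#' @slot fraction mmol superoxide produced per mmol O2 consumed by the
#'   targeted electron-chain reactions.
#' @slot etcReactionIds the rewritten reactions.
#' @slot leakSinkId id of the added superoxide leak sink.
#' @export
setClass("SuperoxideChallenge",
  representation(fraction = "numeric", etcReactionIds = "character",
                 leakSinkId = "character"))

setMethod("show", "SuperoxideChallenge", function(object) {
  cat("SuperoxideChallenge: fraction =", object@fraction, "on",
      length(object@etcReactionIds), "electron-chain reaction(s); leak sink",
      object@leakSinkId, "\n")
})
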