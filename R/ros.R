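## Superoxide challenge and fate accounting.
##
## The challenge rewrites the stoichiometry of the mitochondrial
## electron-chain reactions so that a fixed fraction of the oxygen they
## consume is released as mitochondrial superoxide instead of being fully
## reduced to water (oxygen atoms are conserved: each diverted O2 removes one
## O2-worth of product water). An irreversible superoxide leak sink keeps the
## challenged model feasible when detoxification saturates; flux through that
## sink operationalises "leakage".

.findSpecies <- function(model, formula, compartment, charge = NULL) {
  met <- model@metabolites
  hit <- !is.na(met$formula) & met$formula == formula &
    met$compartment == compartment
  if (!is.null(charge)) hit <- hit & !is.na(met$charge) & met$charge == charge
  met$id[hit]
}

#' Impose mitochondrial superoxide production
#'
#' Rewrites each targeted electron-chain reaction so that, per unit flux,
#' \code{fraction} of its O2 consumption is diverted to mitochondrial
#' superoxide: the reaction gains \code{fraction * |O2 coefficient|}
#' superoxide product and loses twice that much product water (conserving O
#' atoms). A superoxide leak sink is added. The default fraction of 0.02
#' imposes 2\% superoxide production per consumed mmol oxygen.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param fraction mmol superoxide per mmol O2 consumed, in [0, 1].
#' @param etcReactions ids of the electron-chain reactions to rewrite;
#'   by default every reaction that consumes O2 in the mitochondrial
#'   compartment.
#' @param mitoCompartment compartment id of the mitochondrion, default "m".
#' @return List with \code{model} (the challenged
#'   \linkS4class{MetabolicModel}) and \code{challenge}
#'   (a \linkS4class{SuperoxideChallenge}).
#' @export
addSuperoxideCoupling <- function(model, fraction = 0.02,
                                  etcReactions = NULL,
                                  mitoCompartment = "m") {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  met <- model@metabolites
  o2m <- .findSpecies(model, "O2", mitoCompartment, charge = 0)
  if (length(o2m) == 0)
    o2m <- .findSpecies(model, "O2", mitoCompartment)
  o2m <- setdiff(o2m, .findSpecies(model, "O2", mitoCompartment, charge = -1))
  if (length(o2m) == 0)
    stop("no mitochondrial O2 species in model")
  h2om <- .findSpecies(model, "H2O", mitoCompartment)
  S <- as.matrix(model@stoichiometry)
  if (is.null(etcReactions)) {
    consumesO2 <- which(colSums(S[o2m, , drop = FALSE] < 0) > 0)
    etcReactions <- model@reactions$id[consumesO2]
  }
  if (length(etcReactions) == 0)
    stop("no mitochondrial O2-consuming electron-chain reaction found")
  jx <- match(etcReactions, model@reactions$id)
  if (anyNA(jx))
    stop("unknown electron-chain reaction(s): ",
         paste(etcReactions[is.na(jx)], collapse = ", "))

  ## superoxide species: O2 with charge -1 in the mitochondrion; created if
  ## the model does not carry one
  o2s <- .findSpecies(model, "O2", mitoCompartment, charge = -1)
  if (length(o2s) == 0) {
    o2s <- paste0("o2s_", mitoCompartment)
    met <- rbind(met, data.frame(id = o2s, name = "superoxide anion",
                                 compartment = mitoCompartment,
                                 formula = "O2", charge = -1L))
    S <- rbind(S, stats::setNames(rep(0, ncol(S)), NULL))
    rownames(S)[nrow(S)] <- o2s
  } else {
    o2s <- o2s[1]
  }

  for (j in jx) {
    a <- sum(S[o2m, j])
    if (a >= 0)
      stop("reaction ", model@reactions$id[j],
           " does not consume mitochondrial O2")
    divert <- fraction * (-a)
    S[o2s, j] <- S[o2s, j] + divert
    if (divert > 0) {
      wat <- h2om[which(S[h2om, j] > 0)]
      if (length(wat) == 0)
        stop("reaction ", model@reactions$id[j],
             " has no product water to rebalance against")
      wat <- wat[1]
      if (S[wat, j] < 2 * divert - 1e-12)
        stop("reaction ", model@reactions$id[j],
             " produces too little water to divert ", divert, " O2")
      S[wat, j] <- S[wat, j] - 2 * divert
    }
  }

  leakId <- paste0("SINK_", o2s)
  rxns <- c(
    lapply(seq_len(nrow(model@reactions)), function(q) {
      idx <- which(S[, q] != 0)
      list(id = model@reactions$id[q], name = model@reactions$name[q],
           stoichiometry = stats::setNames(S[idx, q], rownames(S)[idx]),
           lower_bound = model@reactions$lower_bound[q],
           upper_bound = model@reactions$upper_bound[q],
           gpr = model@reactions$gpr[q],
           subsystem = model@reactions$subsystem[q])
    }),
    list(list(id = leakId, name = "superoxide leak sink",
              stoichiometry = stats::setNames(-1, o2s),
              lower_bound = 0, upper_bound = 1000,
              gpr = "", subsystem = "ros_leak"))
  )
  challenged <- MetabolicModel(met, rxns, objective = model@objective,
                               genes = model@genes)
  list(model = challenged,
       challenge = new("SuperoxideChallenge", fraction = fraction,
                       etcReactionIds = model@reactions$id[jx],
                       leakSinkId = leakId))
}

#' Superoxide fate accounting over a flux sample set
#'
#' Decomposes, per sample, the total superoxide production into the four
#' fates: dismutation (SOD), direct ascorbate detoxification, the
#' glutathione pathway, and leakage through the added sink. All components
#' are reported in superoxide equivalents (mmol superoxide/gDW/h), so at
#' steady state they sum exactly to production.
#'
#' Fate membership defaults to the model's subsystem annotation
#' (\code{"sod"}, \code{"ascorbate_detox"}, \code{"glutathione_detox"}) and
#' can be overridden per model.
#'
#' @param model the challenged \linkS4class{MetabolicModel}.
#' @param challenge the matching \linkS4class{SuperoxideChallenge}.
#' @param sampleSet a \linkS4class{FluxSampleSet} drawn from \code{model}.
#' @param sodReactions,ascorbateReactions,glutathioneReactions optional
#'   explicit reaction-id overrides for the three detox categories.
#' @return List with \code{summary} (data.frame: component, mean, sd, q25,
#'   q75), \code{perSample} (n-by-5 matrix), and \code{maxResidual}
#'   (largest per-sample balance violation).
#' @export
superoxideFate <- function(model, challenge, sampleSet,
                           sodReactions = NULL,
                           ascorbateReactions = NULL,
                           glutathioneReactions = NULL) {
  if (sampleSet@modelHash != modelHash(model))
    stop("samples were drawn from a different model (hash mismatch)")
  rxn <- model@reactions
  bySub <- function(tag) rxn$id[rxn$subsystem == tag]
  sodReactions <- sodReactions %||% bySub("sod")
  ascorbateReactions <- ascorbateReactions %||% bySub("ascorbate_detox")
  glutathioneReactions <- glutathioneReactions %||% bySub("glutathione_detox")

  ## net superoxide turnover of each reaction (summed over all superoxide
  ## species, so pure transport cancels out)
  met <- model@metabolites
  o2sRows <- which(!is.na(met$formula) & met$formula == "O2" &
                   !is.na(met$charge) & met$charge == -1)
  if (length(o2sRows) == 0) stop("model carries no superoxide species")
  w <- Matrix::colSums(model@stoichiometry[o2sRows, , drop = FALSE])
  X <- sampleSet@samples[, rxn$id, drop = FALSE]
  turnover <- X * matrix(w, nrow(X), length(w), byrow = TRUE)

  production <- rowSums(pmax(turnover, 0))
  consumed <- -pmin(turnover, 0)
  pick <- function(ids) if (length(ids)) rowSums(consumed[, ids, drop = FALSE]) else
    numeric(nrow(X))
  sod <- pick(sodReactions)
  asc <- pick(ascorbateReactions)
  gsh <- pick(glutathioneReactions)
  leak <- consumed[, challenge@leakSinkId]
  residual <- max(abs(production - (sod + asc + gsh + leak)))

  per <- cbind(production = production, sod_total = sod,
               ascorbate_detox = asc, glutathione_path = gsh,
               leakage = leak)
  summ <- data.frame(
    component = colnames(per),
    mean = colMeans(per),
    sd = apply(per, 2, stats::sd),
    q25 = apply(per, 2, stats::quantile, 0.25),
    q75 = apply(per, 2, stats::quantile, 0.75),
    row.names = NULL
  )
  list(summary = summ, perSample = per, maxResidual = residual)
}

#' NADPH production capacity
#'
#' Sink-reaction probe of the maximal NADPH production rate, the readout
#' that gauges how well a model can sustain NADPH-dependent ascorbate
#' recovery (glutaredoxin) and other reductive defence. Because NADP(H) is a
#' conserved moiety, the probe is the redox demand \code{nadph -> nadp}
#' (maximal sustainable oxidation of newly produced NADPH); a bare removal
#' sink could never carry steady-state flux. NADPH species are located by id
#' prefix \code{"nadph_"} within the requested compartments and paired with
#' the corresponding \code{"nadp_"} species.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param compartments compartments whose NADPH pools count, default cytosol.
#' @param metaboliteIds optional explicit NADPH metabolite ids (overrides the
#'   compartment search).
#' @return Maximal summed demand flux (mmol/gDW/h).
#' @export
nadphCapacity <- function(model, compartments = "c", metaboliteIds = NULL) {
  met <- model@metabolites
  ids <- metaboliteIds %||%
    met$id[grepl("^nadph_", met$id) & met$compartment %in% compartments]
  if (length(ids) == 0) stop("no NADPH species found in compartment(s) ",
                             paste(compartments, collapse = ", "))
  lp <- .lpData(model)
  S <- lp$S
  for (id in ids) {
    S <- cbind(S, 0)
    S[match(id, met$id), ncol(S)] <- -1
    nadp <- sub("nadph_", "nadp_", id, fixed = TRUE)
    if (nadp %in% met$id) S[match(nadp, met$id), ncol(S)] <- 1
  }
  k <- length(ids)
  obj <- c(numeric(length(lp$ids)), rep(1, k))
  res <- solveLP(obj, S, rep(0, nrow(S)),
                 c(lp$lb, rep(0, k)), c(lp$ub, rep(1000, k)))
  if (res$status != "optimal")
    stop("NADPH-capacity LP is ", res$status)
  res$objval
}
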