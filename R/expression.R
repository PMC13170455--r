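## Transcriptome integration: replicate averaging, GPR-based reaction scores,
## expression-driven core selection, and eFlux bound scaling.

#' Read an expression profile from a two-column TSV
#'
#' Expected columns: \code{gene_id}, \code{value} (non-negative).
#'
#' @param path TSV path.
#' @param label cell-type label to attach.
#' @return An \linkS4class{ExpressionProfile}.
#' @export
readExpressionProfile <- function(path, label = "") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "value") %in% names(tab)))
  ExpressionProfile(stats::setNames(as.numeric(tab$value), tab$gene_id),
                    label = label)
}

#' Write an expression profile to TSV
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param path output path.
#' @export
writeExpressionProfile <- function(profile, path) {
  utils::write.table(
    data.frame(gene_id = names(profile@values), value = unname(profile@values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean expression profile over replicates
#'
#' Per-gene arithmetic mean over the union of gene ids; a gene absent from a
#' replicate counts as 0 in that replicate (not detected).
#'
#' @param replicates non-empty list of \linkS4class{ExpressionProfile}s.
#' @return An \linkS4class{ExpressionProfile} with \code{nReplicates} set to
#'   the total replicate count.
#' @export
meanExpression <- function(replicates) {
  if (length(replicates) == 0) stop("no replicates given")
  allGenes <- unique(unlist(lapply(replicates, function(p) names(p@values))))
  acc <- stats::setNames(numeric(length(allGenes)), allGenes)
  for (p in replicates) acc[names(p@values)] <- acc[names(p@values)] + p@values
  ExpressionProfile(acc / length(replicates),
                    label = replicates[[1]]@label,
                    nReplicates = sum(vapply(replicates,
                                             function(p) p@nReplicates, 1L)))
}

#' Reaction activity scores from expression and GPR rules
#'
#' Evaluates every reaction's GPR against the expression profile
#' (AND = min, OR = max; genes absent from the profile count as 0).
#' Reactions without a GPR score \code{NA} ("missing").
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param expr an \linkS4class{ExpressionProfile}.
#' @return Named numeric vector of scores (NA = no GPR), one per reaction.
#' @export
gprScore <- function(model, expr) {
  rxn <- model@reactions
  vals <- expr@values
  out <- vapply(seq_len(nrow(rxn)), function(i) {
    tryCatch(evalGPR(rxn$gpr[i], vals),
             error = function(e) stop("reaction ", rxn$id[i], ": ",
                                      conditionMessage(e)))
  }, 0)
  stats::setNames(out, rxn$id)
}

#' Select an expression-supported core set
#'
#' The core is the union of the mandatory reactions and every scored reaction
#' whose score reaches the given quantile of all non-missing scores.
#' Reactions without a GPR can only enter through the mandatory set.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param scores output of \code{\link{gprScore}}.
#' @param thresholdQuantile quantile in (0, 1), default 0.75.
#' @param mandatory \linkS4class{CoreSet} of reactions always included
#'   (biomass, ATP demand, key exchanges).
#' @return A \linkS4class{CoreSet} (epsilon inherited from \code{mandatory}).
#' @export
selectCore <- function(model, scores, thresholdQuantile = 0.75, mandatory) {
  if (thresholdQuantile <= 0 || thresholdQuantile >= 1)
    stop("thresholdQuantile must be in (0, 1)")
  stopifnot(all(names(scores) %in% model@reactions$id))
  sc <- scores[!is.na(scores)]
  thr <- stats::quantile(sc, thresholdQuantile, names = FALSE)
  CoreSet(union(mandatory@reactionIds, names(sc)[sc >= thr]),
          epsilon = mandatory@epsilon)
}

#' eFlux: scale reaction bounds by expression
#'
#' Each reaction with a non-missing activity score s has its upper bound set
#' to \code{vMax * s / max(s)}; reversible reactions get the symmetric
#' negative lower bound, irreversible ones 0. Reactions without a GPR and
#' exchange reactions keep their bounds: eFlux constrains enzymes, while the
#' medium governs uptake.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param scores output of \code{\link{gprScore}} (on the same model).
#' @param vMax flux scale, default 1000 mmol/gDW/h.
#' @return A bound-scaled copy of the model.
#' @export
efluxBounds <- function(model, scores, vMax = 1000) {
  stopifnot(vMax > 0)
  if (all(is.na(scores))) stop("all reaction scores are missing")
  sMax <- max(scores, na.rm = TRUE)
  if (sMax <= 0) stop("maximal reaction score is not positive")
  ex <- exchangeReactions(model)
  rxn <- model@reactions
  for (i in seq_len(nrow(rxn))) {
    s <- scores[rxn$id[i]]
    if (is.na(s) || rxn$id[i] %in% ex) next
    bound <- vMax * unname(s) / sMax
    rxn$upper_bound[i] <- bound
    rxn$lower_bound[i] <- if (rxn$lower_bound[i] < 0) -bound else 0
  }
  model@reactions <- rxn
  model
}
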