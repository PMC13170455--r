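#' Stable hash of a metabolic model
#'
#' Hashes the parts of a model that define its flux space (ids, bounds,
#' stoichiometry, GPRs, objective). Used to tie flux samples and fate reports
#' to the exact model they were computed from.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return Character hash.
#' @export
modelHash <- function(model) {
  rlang::hash(list(model@metabolites$id, model@metabolites$compartment,
                   model@reactions$id, model@reactions$lower_bound,
                   model@reactions$upper_bound, model@reactions$gpr,
                   as.matrix(model@stoichiometry), model@objective))
}

#' Parse a chemical formula into element counts
#'
#' Supports fractional counts (e.g. pooled biomass pseudo-species such as
#' \code{"C20.9H46.3N4O16.6P0.5"}).
#'
#' @param formula formula string.
#' @return Named numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(numeric(), character()))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, el, sum)[unique(el)]
}

#' Elemental balance of every reaction
#'
#' For each non-exchange reaction with fully formula-annotated participants,
#' reports the net imbalance of the requested elements (0 everywhere for a
#' mass-balanced network; exchange and sink pseudo-reactions are skipped).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param elements elements to check, default C and O.
#' @return data.frame with one row per checked reaction and one column per
#'   element (net produced minus consumed atoms per unit flux).
#' @export
elementalBalance <- function(model, elements = c("C", "O")) {
  met <- model@metabolites
  S <- model@stoichiometry
  ex <- exchangeReactions(model)
  counts <- lapply(met$formula, parseFormula)
  nnz <- Matrix::colSums(S != 0)
  rows <- list()
  for (j in seq_len(nrow(model@reactions))) {
    rid <- model@reactions$id[j]
    ## exchange, sink and demand pseudo-reactions touch one species and are
    ## unbalanced by construction
    if (rid %in% ex || nnz[j] == 1) next
    idx <- which(S[, j] != 0)
    if (any(is.na(met$formula[idx]))) next
    bal <- vapply(elements, function(e) {
      sum(vapply(idx, function(i) {
        ct <- counts[[i]][e]
        if (is.na(ct)) 0 else ct * S[i, j]
      }, 0))
    }, 0)
    rows[[rid]] <- bal
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- elements
  out
}
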