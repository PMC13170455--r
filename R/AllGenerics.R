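#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))
#' @export
setGeneric("genes", function(object, ...) standardGeneric("genes"))
#' @export
setGeneric("objectiveReaction", function(object) standardGeneric("objectiveReaction"))
#' @export
setGeneric("objectiveReaction<-", function(object, value) standardGeneric("objectiveReaction<-"))
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))
#' @export
setGeneric("setBounds", function(object, ids, lower = NULL, upper = NULL)
  standardGeneric("setBounds"))
#' @export
setGeneric("stoichiometricMatrix", function(object) standardGeneric("stoichiometricMatrix"))
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))
#' @export
setGeneric("fluxRanges", function(object) standardGeneric("fluxRanges"))
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
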