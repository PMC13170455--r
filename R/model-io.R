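## Readers and writers for the two interchange formats used by published
## genome-scale models: SBML Level 3 with the fbc package, and COBRA-style
## JSON. Identifiers are written with the conventional R_/M_/G_ prefixes in
## SBML and stripped again on read, so models round-trip unchanged and
## deposited models load with their usual ids.

#' Read a metabolic model from file
#'
#' @param path file path.
#' @param format \code{"sbml"} or \code{"json"}; default guesses from the
#'   file extension.
#' @param strict if \code{TRUE} (default) any validation problem is an error;
#'   otherwise problems are reported as warnings and the model returned as-is,
#'   which accommodates hand-curated models with minor inconsistencies.
#' @return A \linkS4class{MetabolicModel}.
#' @export
readMetabolicModel <- function(path, format = c("auto", "sbml", "json"),
                               strict = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  model <- switch(format,
    json = .readModelJSON(path),
    sbml = .readModelSBML(path)
  )
  msgs <- validateModelInternal(model)
  if (length(msgs)) {
    if (strict) stop("model validation failed: ", paste(msgs, collapse = "; "))
    warning("model validation problems (permissive mode): ",
            paste(msgs, collapse = "; "))
  }
  model
}

#' Write a metabolic model to file
#'
#' Output is canonical (fixed element order and number formatting), so two
#' writes of the same model are byte-identical.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output path.
#' @param format \code{"sbml"} or \code{"json"}; default guesses from the
#'   file extension.
#' @return \code{path}, invisibly.
#' @export
writeMetabolicModel <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  validObject(model)
  switch(format,
    json = .writeModelJSON(model, path),
    sbml = .writeModelSBML(model, path)
  )
  invisible(path)
}

.num <- function(x) {
  ## canonical number formatting shared by both writers
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE), "")
}

## --------------------------- COBRA JSON ------------------------------------

.readModelJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a COBRA JSON model (missing metabolites/reactions): ", path)
  met <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, ""),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, ""),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "", ""),
    formula = vapply(doc$metabolites, function(m)
      if (is.null(m$formula)) NA_character_ else as.character(m$formula), ""),
    charge = vapply(doc$metabolites, function(m)
      if (is.null(m$charge)) NA_integer_ else as.integer(m$charge), 1L),
    stringsAsFactors = FALSE
  )
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective <<- r$id
    list(id = r$id, name = r$name %||% r$id,
         stoichiometry = unlist(r$metabolites),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gpr = r$gene_reaction_rule %||% "",
         subsystem = r$subsystem %||% "")
  })
  if (is.null(objective)) objective <- rxns[[1]]$id
  genes <- if (!is.null(doc$genes))
    vapply(doc$genes, function(g) g$id, "") else NULL
  MetabolicModel(met, rxns, objective = objective, genes = genes)
}

.writeModelJSON <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  mets <- lapply(seq_len(nrow(met)), function(i) {
    out <- list(id = met$id[i], name = met$name[i],
                compartment = met$compartment[i])
    if (!is.na(met$formula[i])) out$formula <- met$formula[i]
    if (!is.na(met$charge[i])) out$charge <- met$charge[i]
    out
  })
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    idx <- which(S[, j] != 0)
    st <- as.list(S[idx, j])
    names(st) <- met$id[idx]
    list(id = rxn$id[j], name = rxn$name[j], metabolites = st,
         lower_bound = rxn$lower_bound[j], upper_bound = rxn$upper_bound[j],
         gene_reaction_rule = rxn$gpr[j], subsystem = rxn$subsystem[j],
         objective_coefficient = if (rxn$id[j] == model@objective) 1 else 0)
  })
  doc <- list(id = "model",
              compartments = as.list(stats::setNames(
                sort(unique(met$compartment)), sort(unique(met$compartment)))),
              metabolites = mets, reactions = rxns,
              genes = lapply(model@genes, function(g) list(id = g, name = g)),
              version = "1")
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ----------------------------- SBML-FBC ------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbmlSafe <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.writeModelSBML <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry

  root <- xml2::xml_new_root("sbml",
    xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(root, "model", id = "model", "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in sort(unique(met$compartment)))
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    attrs <- list(id = paste0("M_", .sbmlSafe(met$id[i])), name = met$name[i],
                  compartment = met$compartment[i],
                  hasOnlySubstanceUnits = "false", boundaryCondition = "false",
                  constant = "false")
    if (!is.na(met$formula[i])) attrs[["fbc:chemicalFormula"]] <- met$formula[i]
    if (!is.na(met$charge[i])) attrs[["fbc:charge"]] <- as.character(met$charge[i])
    do.call(xml2::xml_add_child, c(list(sps, "species"), attrs))
  }

  ## one parameter per distinct bound value
  vals <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(vals)), .num(vals))
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in vals)
    xml2::xml_add_child(pars, "parameter", id = pid[[.num(v)]],
                        value = .num(v), constant = "true",
                        sboTerm = "SBO:0000626")

  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(rxn))) {
    rnode <- xml2::xml_add_child(rxns, "reaction",
      id = paste0("R_", .sbmlSafe(rxn$id[j])), name = rxn$name[j],
      reversible = if (rxn$lower_bound[j] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid[[.num(rxn$lower_bound[j])]],
      "fbc:upperFluxBound" = pid[[.num(rxn$upper_bound[j])]])
    if (nzchar(rxn$subsystem[j])) {
      notes <- xml2::xml_add_child(rnode, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", rxn$subsystem[j]))
    }
    idx <- which(S[, j] != 0)
    coef <- S[idx, j]
    if (any(coef < 0)) {
      lr <- xml2::xml_add_child(rnode, "listOfReactants")
      for (k in idx[coef < 0])
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", .sbmlSafe(met$id[k])),
          stoichiometry = .num(-S[k, j]), constant = "true")
    }
    if (any(coef > 0)) {
      lp <- xml2::xml_add_child(rnode, "listOfProducts")
      for (k in idx[coef > 0])
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", .sbmlSafe(met$id[k])),
          stoichiometry = .num(S[k, j]), constant = "true")
    }
    if (nzchar(rxn$gpr[j])) {
      ga <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      .writeGPRNode(ga, parseGPR(rxn$gpr[j]))
    }
  }

  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
    "fbc:reaction" = paste0("R_", .sbmlSafe(model@objective)),
    "fbc:coefficient" = "1")

  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model@genes)
    xml2::xml_add_child(gps, "fbc:geneProduct",
      "fbc:id" = paste0("G_", .sbmlSafe(g)), "fbc:label" = g)

  xml2::write_xml(root, path)
}

.writeGPRNode <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", .sbmlSafe(tree)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (a in tree$args) .writeGPRNode(node, a)
  }
}

.readModelSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  attrOf <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }
  stripPrefix <- function(x, pre) ifelse(startsWith(x, pre),
                                         substring(x, nchar(pre) + 1), x)

  spNodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (length(spNodes) == 0) stop("no species in ", path)
  met <- data.frame(
    id = stripPrefix(xml2::xml_attr(spNodes, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(spNodes, "name")),
                  stripPrefix(xml2::xml_attr(spNodes, "id"), "M_"),
                  xml2::xml_attr(spNodes, "name")),
    compartment = xml2::xml_attr(spNodes, "compartment"),
    formula = vapply(spNodes, attrOf, "", name = "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(spNodes, attrOf, "", name = "charge"))),
    stringsAsFactors = FALSE
  )

  parNodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                            xml2::xml_attr(parNodes, "id"))

  gpNodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gpLabel <- stats::setNames(
    ifelse(is.na(vapply(gpNodes, attrOf, "", name = "label")),
           stripPrefix(vapply(gpNodes, attrOf, "", name = "id"), "G_"),
           vapply(gpNodes, attrOf, "", name = "label")),
    vapply(gpNodes, attrOf, "", name = "id"))

  readGPR <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attrOf(node, "geneProduct")
      lbl <- gpLabel[ref]
      return(if (is.na(lbl)) stripPrefix(ref, "G_") else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      sub <- readGPR(k)
      if (xml2::xml_name(k) %in% c("and", "or")) paste0("(", sub, ")") else sub
    }, "")
    paste(parts, collapse = paste0(" ", nm, " "))
  }

  rxNodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxNodes) == 0) stop("no reactions in ", path)
  rxns <- lapply(rxNodes, function(rn) {
    rid <- stripPrefix(xml2::xml_attr(rn, "id"), "R_")
    lbp <- attrOf(rn, "lowerFluxBound")
    ubp <- attrOf(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parVal)) parVal[[lbp]] else -1000
    ub <- if (!is.na(ubp) && ubp %in% names(parVal)) parVal[[ubp]] else 1000
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      mid <- stripPrefix(xml2::xml_attr(sr, "species"), "M_")
      st[mid] <- (if (mid %in% names(st)) st[mid] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      mid <- stripPrefix(xml2::xml_attr(sr, "species"), "M_")
      st[mid] <- (if (mid %in% names(st)) st[mid] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    ga <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(ga, "xml_missing")) "" else {
      kids <- xml2::xml_children(ga)
      if (length(kids)) readGPR(kids[[1]]) else ""
    }
    note <- xml2::xml_find_first(rn, ".//s:notes//*[starts-with(text(), 'SUBSYSTEM:')]", ns)
    subsystem <- if (inherits(note, "xml_missing")) "" else
      trimws(sub("^SUBSYSTEM:", "", xml2::xml_text(note)))
    list(id = rid, name = xml2::xml_attr(rn, "name") %||% rid,
         stoichiometry = st, lower_bound = lb, upper_bound = ub,
         gpr = gpr, subsystem = subsystem)
  })

  fo <- xml2::xml_find_first(mdl,
    ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  objective <- if (inherits(fo, "xml_missing"))
    rxns[[1]]$id else stripPrefix(attrOf(fo, "reaction"), "R_")

  genes <- unname(gpLabel)
  MetabolicModel(met, rxns, objective = objective,
                 genes = if (length(genes)) genes else NULL)
}

## ------------------------------ medium -------------------------------------

#' Read a medium specification
#'
#' A medium is a named non-negative vector of maximal uptake rates
#' (mmol/gDW/h) keyed by exchange-reaction id, stored on disk as a two-column
#' TSV (\code{exchange_id}, \code{max_uptake}).
#'
#' @param path TSV path.
#' @return Named numeric vector.
#' @export
readMedium <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("exchange_id", "max_uptake") %in% names(tab)))
  med <- stats::setNames(as.numeric(tab$max_uptake), tab$exchange_id)
  if (any(med < 0)) stop("medium uptake rates must be >= 0")
  med
}

#' Write a medium specification
#' @param medium named non-negative numeric vector (exchange id to rate).
#' @param path output TSV path.
#' @export
writeMedium <- function(medium, path) {
  utils::write.table(
    data.frame(exchange_id = names(medium), max_uptake = unname(medium)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Constrain a model with an uptake medium
#'
#' Closes the uptake direction of every exchange reaction not listed in the
#' medium and caps listed exchanges at their stated maximal uptake
#' (uptake = negative exchange flux, so the lower bound becomes
#' \code{max(lb, -rate)}). Secretion bounds are untouched, and no bound is
#' ever widened beyond what the model already allows.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium named non-negative numeric vector keyed by exchange ids.
#' @return A constrained copy of the model.
#' @export
applyMedium <- function(model, medium) {
  if (any(medium < 0)) stop("medium uptake rates must be >= 0")
  ex <- exchangeReactions(model)
  bad <- intersect(setdiff(names(medium), ex), model@reactions$id)
  if (length(bad))
    stop("medium entries are not exchange reactions: ",
         paste(bad, collapse = ", "))
  ## entries whose exchange was pruned from a context-specific model are
  ## silently inapplicable
  medium <- medium[names(medium) %in% ex]
  idx <- match(ex, model@reactions$id)
  lb <- model@reactions$lower_bound[idx]
  rate <- ifelse(ex %in% names(medium), medium[ex], 0)
  model@reactions$lower_bound[idx] <- pmax(lb, -rate)
  model
}
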