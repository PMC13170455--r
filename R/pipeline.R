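## Config-driven orchestration of the whole workflow: expression averaging,
## reaction scoring, core selection, consistency pre-pass, fastcore
## extraction, medium constraints, eFlux scaling, then FBA/FVA, capacity
## analyses, the inhibitor panel, the superoxide challenge with fate
## accounting, and flux-distribution summaries. One config drives everything
## and all outputs carry seeds and model hashes for provenance.

#' Assemble and validate a pipeline configuration
#'
#' @param model \code{"toy"} or the path of a model file (SBML/JSON).
#' @param expression named list (cell type -> list of
#'   \linkS4class{ExpressionProfile}s or TSV paths). \code{NULL} simulates
#'   the three shipped archetypes.
#' @param medium \code{"default"} or a medium TSV path.
#' @param thresholdQuantile expression core-selection quantile, default 0.75.
#' @param epsilon consistency tolerance, default 1e-4 mmol/gDW/h.
#' @param vMax eFlux flux scale, default 1000 mmol/gDW/h.
#' @param panel inhibitor panel, default \code{\link{defaultInhibitorPanel}}.
#' @param mandatory mandatory core reactions, default
#'   \code{\link{mandatoryCore}}.
#' @param superoxideFraction superoxide per consumed O2, default 0.02.
#' @param samplingN,samplingWarmup,samplingThinning sampler settings.
#' @param seed master seed; archetype and sampling seeds derive from it.
#' @param outDir output directory (created); \code{NULL} for no file output.
#' @return Validated config (list of class \code{RunConfig}).
#' @export
runConfig <- function(model = "toy", expression = NULL, medium = "default",
                      thresholdQuantile = 0.75, epsilon = 1e-4, vMax = 1000,
                      panel = defaultInhibitorPanel(),
                      mandatory = mandatoryCore(epsilon),
                      superoxideFraction = 0.02,
                      samplingN = 10000L, samplingWarmup = 1000L,
                      samplingThinning = 100L,
                      seed = 1L, outDir = NULL) {
  if (!identical(model, "toy") && !file.exists(model))
    stop("model file not found: ", model)
  if (!identical(medium, "default") && !file.exists(medium))
    stop("medium file not found: ", medium)
  if (!is.null(expression)) {
    for (ct in names(expression)) for (p in expression[[ct]]) {
      if (is.character(p) && !file.exists(p))
        stop("expression file not found: ", p)
    }
  }
  stopifnot(thresholdQuantile > 0, thresholdQuantile < 1, epsilon > 0,
            vMax > 0, superoxideFraction >= 0, superoxideFraction <= 1,
            samplingN >= 1, samplingThinning >= 1)
  structure(list(model = model, expression = expression, medium = medium,
                 thresholdQuantile = thresholdQuantile, epsilon = epsilon,
                 vMax = vMax, panel = panel, mandatory = mandatory,
                 superoxideFraction = superoxideFraction,
                 samplingN = as.integer(samplingN),
                 samplingWarmup = as.integer(samplingWarmup),
                 samplingThinning = as.integer(samplingThinning),
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

.writeTsv <- function(df, dir, file) {
  if (!is.null(dir))
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Run the full comparative pipeline
#'
#' For every cell type: replicate averaging, GPR scoring, expression-based
#' core selection, consistency pre-pass, fastcore extraction, medium
#' constraints and eFlux scaling; then biomass FBA, ATP/NADPH/lactate
#' capacities, FVA at optimal biomass, the inhibitor panel (biomass and ATP
#' objectives), flux sampling with distribution summaries for the key
#' reactions, and the superoxide challenge with fate accounting. The only
#' difference between cell-type models is the expression input.
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @return Invisibly, a named list per cell type with the context model and
#'   all result tables; writes TSV tables and a JSON manifest when
#'   \code{config$outDir} is set.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir <- config$outDir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  base <- if (identical(config$model, "toy")) buildToyNetwork() else
    readMetabolicModel(config$model)
  medium <- if (identical(config$medium, "default")) defaultMedium() else
    readMedium(config$medium)

  expr <- config$expression
  if (is.null(expr)) {
    labels <- c("alps_like", "ebv_like", "hd_like")
    expr <- stats::setNames(lapply(seq_along(labels), function(i)
      simulateExpression(archetypeSpec(labels[i],
                                       seed = config$seed + i))), labels)
  }

  consistent <- fastcc(base, config$epsilon)

  results <- list()
  for (ci in seq_along(expr)) {
    cellType <- names(expr)[ci]
    reps <- lapply(expr[[cellType]], function(p)
      if (is.character(p)) readExpressionProfile(p, label = cellType) else p)
    prof <- meanExpression(reps)
    scores <- gprScore(consistent, prof)
    core <- selectCore(consistent, scores, config$thresholdQuantile,
                       config$mandatory)
    context <- fastcore(core, consistent)
    context <- applyMedium(context, medium)
    ctxScores <- scores[context@reactions$id]
    context <- efluxBounds(context, ctxScores, vMax = config$vMax)

    biomass <- fba(context)
    if (solverStatus(biomass) != "optimal")
      stop("stage fba(biomass) failed for ", cellType, ": ",
           solverStatus(biomass))
    atp <- atpCapacity(context)
    nadph <- nadphCapacity(context)
    lactate <- if ("EX_lac" %in% context@reactions$id)
      secretionCapacity(context, "EX_lac") else 0
    ranges <- fva(context, fractionOfOptimum = 1)
    panelBiomass <- inhibitorPanel(context, config$panel, "biomass")
    panelAtp <- inhibitorPanel(context, config$panel, "atp")
    anox <- anoxia(context)
    anoxiaAtp <- atpCapacity(anox)

    sampleSeed <- config$seed + 100L * ci
    smp <- sampleFluxes(context, n = config$samplingN, seed = sampleSeed,
                        warmup = config$samplingWarmup,
                        thinning = config$samplingThinning)
    keyRxns <- intersect(c("HEX1", "EX_lac", "GSS", "HMOX", "ETC"),
                         context@reactions$id)
    summaries <- summarizeDistribution(smp, keyRxns)

    ros <- addSuperoxideCoupling(context, config$superoxideFraction)
    rosSamples <- sampleFluxes(ros$model, n = config$samplingN,
                               seed = sampleSeed + 1L,
                               warmup = config$samplingWarmup,
                               thinning = config$samplingThinning)
    fate <- superoxideFate(ros$model, ros$challenge, rosSamples)

    res <- list(
      cellType = cellType, model = context, scores = scores, core = core,
      biomass = objectiveValue(biomass), atpCapacity = atp,
      nadphCapacity = nadph, lactateCapacity = lactate,
      anoxiaAtp = anoxiaAtp, anoxiaAtpRelative = anoxiaAtp / atp,
      fva = ranges, panelBiomass = panelBiomass, panelAtp = panelAtp,
      samples = smp, sampleSummary = summaries, fate = fate,
      modelHash = modelHash(context), sampleSeed = sampleSeed
    )
    results[[cellType]] <- res

    if (!is.null(dir)) {
      pfx <- function(f) paste0(cellType, "_", f)
      .writeTsv(data.frame(cell_type = cellType,
                           model_hash = res$modelHash,
                           seed = sampleSeed,
                           biomass = res$biomass, atp = atp, nadph = nadph,
                           lactate = lactate, anoxia_atp = anoxiaAtp),
                dir, pfx("capacities.tsv"))
      rngDf <- data.frame(reaction_id = rownames(fluxRanges(ranges)),
                          fluxRanges(ranges), row.names = NULL)
      .writeTsv(rngDf, dir, pfx("fva.tsv"))
      .writeTsv(cbind(cell_type = cellType, panelBiomass), dir,
                pfx("panel_biomass.tsv"))
      .writeTsv(cbind(cell_type = cellType, panelAtp), dir,
                pfx("panel_atp.tsv"))
      .writeTsv(cbind(cell_type = cellType, summaries$stats), dir,
                pfx("sampled_summary.tsv"))
      .writeTsv(cbind(cell_type = cellType, fate$summary), dir,
                pfx("superoxide_fate.tsv"))
      .writeTsv(extractionReport(consistent, context), dir,
                pfx("extraction.tsv"))
    }
  }

  if (!is.null(dir)) {
    manifest <- list(
      seed = config$seed,
      epsilon = config$epsilon,
      thresholdQuantile = config$thresholdQuantile,
      vMax = config$vMax,
      superoxideFraction = config$superoxideFraction,
      sampling = list(n = config$samplingN, warmup = config$samplingWarmup,
                      thinning = config$samplingThinning),
      medium = as.list(medium),
      modelHashes = lapply(results, `[[`, "modelHash")
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}

#' Cross-model comparison report
#'
#' Joins the per-cell-type result tables of one or more pipeline runs into
#' tidy cross-model tables (capacities, panel relative values with failure
#' flags, superoxide-fate components, sampled-flux summaries).
#'
#' @param results result list from \code{\link{runPipeline}}, or a list of
#'   such lists.
#' @return List of data.frames: \code{capacities}, \code{panelBiomass},
#'   \code{panelAtp}, \code{fate}, \code{sampledMeans}.
#' @export
compareModels <- function(results) {
  if (!is.null(results$cellType)) results <- list(results)
  if (is.list(results) && !is.null(results[[1]]$cellType))
    results <- list(results)
  flat <- do.call(c, results)
  capacities <- do.call(rbind, lapply(flat, function(r)
    data.frame(cell_type = r$cellType, biomass = r$biomass,
               atp = r$atpCapacity, nadph = r$nadphCapacity,
               lactate = r$lactateCapacity,
               anoxia_atp_relative = r$anoxiaAtpRelative,
               model_hash = r$modelHash)))
  panelB <- do.call(rbind, lapply(flat, function(r)
    cbind(cell_type = r$cellType, r$panelBiomass)))
  panelA <- do.call(rbind, lapply(flat, function(r)
    cbind(cell_type = r$cellType, r$panelAtp)))
  fate <- do.call(rbind, lapply(flat, function(r)
    cbind(cell_type = r$cellType, r$fate$summary)))
  sampled <- do.call(rbind, lapply(flat, function(r)
    cbind(cell_type = r$cellType, r$sampleSummary$stats)))
  list(capacities = capacities, panelBiomass = panelB, panelAtp = panelA,
       fate = fate, sampledMeans = sampled)
}
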