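#' Assemble a pipeline configuration
#'
#' A plain validated list steering the end-to-end runs. Accepts either
#' in-memory objects (a [MetabolicModel-class], named cluster lists,
#' [FluxSampleSet-class] pairs) or file paths that are loaded at run
#' start; all randomness flows from the seeds recorded here.
#'
#' @param model a [MetabolicModel-class] or a model file path.
#' @param modelFormat "auto", "json" or "sbml" (for a path).
#' @param constraintsLow,constraintsHigh constraint sets
#'   ([constraintSet()]) or TSV paths, one per condition.
#' @param nPoints,stepCount,samplerSeed sampler parameters; `stepCount`
#'   `NULL` means twice the pruned model's reaction count.
#' @param nRepeats,alpha,testSeed,subsample shift-test parameters.
#' @param samples optional list(low=, high=) of [FluxSampleSet-class]
#'   objects that bypasses constrain/prune/sample (e.g. planted fixtures).
#' @param clusters named list or cluster TSV path.
#' @param geneTerms named list or gene-term TSV path.
#' @param connectivityThreshold edge threshold for the cluster arm.
#' @param scenarios list of [ScenarioSpec-class] objects.
#' @param outputDir directory for persisted intermediates; `NULL` keeps
#'   everything in memory.
#' @return the configuration list (class "cnfluxConfig").
#' @export
cnfluxConfig <- function(model = NULL, modelFormat = "auto",
                         constraintsLow = NULL, constraintsHigh = NULL,
                         nPoints = 2000L, stepCount = NULL,
                         samplerSeed = 1L, nRepeats = 100L, alpha = 0.05,
                         testSeed = 1L, subsample = NULL, samples = NULL,
                         clusters = NULL, geneTerms = NULL,
                         connectivityThreshold = 0.9, scenarios = list(),
                         outputDir = NULL) {
  cfg <- list(model = model, modelFormat = modelFormat,
              constraintsLow = constraintsLow,
              constraintsHigh = constraintsHigh, nPoints = nPoints,
              stepCount = stepCount, samplerSeed = samplerSeed,
              nRepeats = nRepeats, alpha = alpha, testSeed = testSeed,
              subsample = subsample, samples = samples, clusters = clusters,
              geneTerms = geneTerms,
              connectivityThreshold = connectivityThreshold,
              scenarios = scenarios, outputDir = outputDir)
  class(cfg) <- "cnfluxConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File fields mirror the [cnfluxConfig()] arguments; paths are resolved
#' relative to the config file's directory.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a "cnfluxConfig" list.
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.character(p) && !file.exists(p))
    file.path(base, p) else p
  for (f in c("model", "constraintsLow", "constraintsHigh", "clusters",
              "geneTerms"))
    if (!is.null(raw[[f]])) raw[[f]] <- resolve(raw[[f]])
  do.call(cnfluxConfig, raw)
}

resolveModel <- function(cfg) {
  if (is(cfg$model, "MetabolicModel")) cfg$model
  else loadModel(cfg$model, cfg$modelFormat)
}

resolveConstraints <- function(x) {
  if (is.null(x)) constraintSet(character(), numeric(), numeric())
  else if (is.character(x)) readConstraintTable(x)
  else x
}

persist <- function(cfg, name, df, seeds = list()) {
  if (is.null(cfg$outputDir)) return(invisible(NULL))
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(df, file.path(cfg$outputDir, paste0(name, ".tsv")),
           config = cfg[setdiff(names(cfg), c("model", "samples"))],
           seeds = seeds)
}

stageMsg <- function(stage) {
  message("[cnflux] ", stage, " (", format(Sys.time(), "%H:%M:%S"), ")")
}

#' Run the flux arm: constrain, prune, sample, test, summarise
#'
#' Executes the two-condition flux analysis: applies the low- and
#' high-carbon constraint sets, prunes blocked reactions, samples both
#' flux spaces, tests every reaction for a distribution shift and
#' summarises hits per display group. Supplying `samples` in the config
#' bypasses the model stages and tests the given matrices directly.
#'
#' @param cfg a [cnfluxConfig()] list.
#' @param cmap optional [CategoryMap-class]; built from the model's
#'   subsystems when omitted.
#' @return list: `results` (per-reaction shift table), `significant`
#'   (reaction ids), `groups` (group summary, when a model is available),
#'   `prunedLow`/`prunedHigh` (reduced models, when sampled here).
#' @export
runFluxArm <- function(cfg, cmap = NULL) {
  out <- list()
  if (is.null(cfg$samples)) {
    stageMsg("constrain + prune")
    model <- resolveModel(cfg)
    mLow <- applyConstraints(model, resolveConstraints(cfg$constraintsLow))
    mHigh <- applyConstraints(model, resolveConstraints(cfg$constraintsHigh))
    pLow <- pruneBlocked(mLow)
    pHigh <- pruneBlocked(mHigh)
    out$prunedLow <- pLow$model; out$prunedHigh <- pHigh$model
    stageMsg("sample low/high")
    sc <- cfg$stepCount %||% (2L * nReactions(pLow$model))
    low <- sampleFluxes(pLow$model, cfg$nPoints, sc,
                        seed = cfg$samplerSeed, condition = "low")
    high <- sampleFluxes(pHigh$model, cfg$nPoints, sc,
                         seed = cfg$samplerSeed + 1L, condition = "high")
  } else {
    model <- if (!is.null(cfg$model)) resolveModel(cfg) else NULL
    low <- cfg$samples$low; high <- cfg$samples$high
  }
  stageMsg("shift test")
  res <- testFluxShifts(low, high, nRepeats = cfg$nRepeats,
                        alpha = cfg$alpha, seed = cfg$testSeed,
                        subsample = cfg$subsample)
  out$results <- res
  out$significant <- res$reaction_id[res$significant]
  persist(cfg, "shift_test", res,
          seeds = list(sampler = cfg$samplerSeed, test = cfg$testSeed))
  if (!is.null(model) &&
      all(res$reaction_id %in% reactionIds(model))) {
    if (is.null(cmap)) cmap <- buildCategoryMap(unique(subsystems(model)))
    stageMsg("group summary")
    out$groups <- suppressWarnings(summarizeGroups(res, model, cmap))
    persist(cfg, "group_summary", out$groups)
  }
  out
}

#' Run the cluster arm: enrichment, C/N flags, connectivity, topology
#'
#' Enriches every cluster against the gene-term table, flags clusters as
#' carbon/nitrogen metabolism, restricts to flagged clusters, extracts
#' substrate and product metabolite sets through the model's GPRs, builds
#' one connectivity graph per side and reports their topology.
#'
#' @param cfg a [cnfluxConfig()] list with `model`, `clusters`,
#'   `geneTerms`.
#' @param cmap optional [CategoryMap-class] covering the term vocabulary;
#'   built from the terms when omitted.
#' @return list: `enrichment`, `flags`, `flagged` (cluster ids),
#'   `graphs` (list substrates/products), `topology` (per side),
#'   `edgeLists` (per side data.frame).
#' @export
runClusterArm <- function(cfg, cmap = NULL) {
  model <- resolveModel(cfg)
  clusters <- if (is.character(cfg$clusters)) readClusterTable(cfg$clusters)
              else cfg$clusters
  geneTerms <- if (is.character(cfg$geneTerms)) readGeneTermTable(cfg$geneTerms)
               else cfg$geneTerms
  stageMsg("enrichment")
  enr <- enrichClusters(clusters, geneTerms, alpha = cfg$alpha)
  persist(cfg, "enrichment", enr)
  if (is.null(cmap)) cmap <- buildCategoryMap(unique(enr$term))
  flags <- flagCNClusters(enr, cmap, alpha = cfg$alpha)
  flagged <- names(flags)[vapply(flags, length, integer(1)) > 0]
  out <- list(enrichment = enr, flags = flags, flagged = flagged,
              graphs = list(), topology = list(), edgeLists = list())
  if (!length(flagged)) {
    stageMsg("no carbon/nitrogen-flagged clusters; empty graphs")
    return(out)
  }
  stageMsg("connectivity")
  for (side in c("substrates", "products")) {
    sets <- clusterMetaboliteSets(clusters[flagged], model, side = side)
    g <- connectivityGraph(sets, threshold = cfg$connectivityThreshold,
                           side = side)
    out$graphs[[side]] <- g
    out$topology[[side]] <- graphTopology(g)
    ed <- igraph::as_data_frame(g, what = "edges")
    out$edgeLists[[side]] <- data.frame(
      cluster_a = ed$from, cluster_b = ed$to,
      score = if (nrow(ed)) ed$weight else numeric(0),
      side = rep(side, nrow(ed)), stringsAsFactors = FALSE)
    persist(cfg, paste0("edges_", side), out$edgeLists[[side]])
    if (!is.null(cfg$outputDir))
      writeGraphML(g, file.path(cfg$outputDir,
                                paste0("connectivity_", side, ".graphml")))
  }
  out
}

#' Run every configured scenario
#'
#' @param cfg a [cnfluxConfig()] list with a `scenarios` list of
#'   [ScenarioSpec-class] objects.
#' @return named list of [ScenarioResult-class] (by scenario label);
#'   per-step TSVs and a breakpoint JSON summary are persisted when
#'   `outputDir` is set.
#' @export
runScenarios <- function(cfg) {
  if (!length(cfg$scenarios)) return(list())
  model <- resolveModel(cfg)
  out <- list()
  summaries <- list()
  for (spec in cfg$scenarios) {
    stageMsg(paste("scenario", spec@scenario))
    res <- runScenario(model, spec)
    out[[spec@scenario]] <- res
    persist(cfg, paste0("scenario_", spec@scenario), res@steps)
    summaries[[spec@scenario]] <- list(
      breakpoint_carbon = res@breakpointCarbon,
      breakpoint_cn_ratio = res@breakpointCNRatio)
  }
  if (!is.null(cfg$outputDir))
    jsonlite::write_json(summaries,
                         file.path(cfg$outputDir, "scenario_breakpoints.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  out
}
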