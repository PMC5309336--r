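#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveId", function(object) standardGeneric("objectiveId"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("subsystems", function(object) standardGeneric("subsystems"))
#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactionBounds", function(object) standardGeneric("reactionBounds"))

#' @rdname FluxSampleSet-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname FluxSampleSet-accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' Accessors for MetabolicModel
#'
#' `reactionIds`/`metaboliteIds` return id vectors; `nReactions`/
#' `nMetabolites` their counts; `stoichiometry` the sparse S matrix
#' (metabolites x reactions); `objectiveId` the biomass reaction id;
#' `geneIds` all gene ids mentioned in GPRs; `subsystems` a named character
#' vector (reaction id -> subsystem); `reactionBounds` a data.frame with
#' `id`, `lower_bound`, `upper_bound`.
#'
#' @param object a [MetabolicModel-class]
#' @return see description per accessor.
#' @name MetabolicModel-accessors
#' @aliases reactionIds metaboliteIds nReactions nMetabolites stoichiometry
#'   objectiveId geneIds subsystems reactionBounds
NULL

setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)
setMethod("nReactions", "MetabolicModel", function(object) nrow(object@reactions))
setMethod("nMetabolites", "MetabolicModel", function(object) nrow(object@metabolites))
setMethod("stoichiometry", "MetabolicModel", function(object) object@stoichiometry)
setMethod("objectiveId", "MetabolicModel", function(object) object@objective)
setMethod("geneIds", "MetabolicModel", function(object)
  sort(unique(unlist(lapply(object@reactions$gpr, gprGenes)))))
setMethod("subsystems", "MetabolicModel", function(object)
  setNames(object@reactions$subsystem, object@reactions$id))
setMethod("reactionBounds", "MetabolicModel", function(object)
  object@reactions[, c("id", "lower_bound", "upper_bound")])

#' Accessors for FluxSampleSet
#'
#' `samples` returns the n_samples x n_reactions flux matrix; `sampleMeta`
#' the metadata list (seed, n_points, step_count, condition).
#'
#' @param object a [FluxSampleSet-class]
#' @name FluxSampleSet-accessors
#' @aliases samples sampleMeta
NULL

setMethod("samples", "FluxSampleSet", function(object) object@samples)
setMethod("sampleMeta", "FluxSampleSet", function(object) object@meta)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nMetabolites(object), "metabolites,",
      nReactions(object), "reactions\n")
  cat("  objective:", object@objective, "\n")
  cat("  genes:", length(geneIds(object)),
      " subsystems:", length(unique(object@reactions$subsystem)), "\n")
  cat("  compartments:", paste(unique(object@metabolites$compartment),
                               collapse = ", "), "\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution [", object@status, "]", sep = "")
  if (object@status == "optimal")
    cat(" objective =", format(object@objectiveValue, digits = 8))
  cat("\n")
})

setMethod("show", "FluxSampleSet", function(object) {
  cat("FluxSampleSet:", nrow(object@samples), "samples x",
      ncol(object@samples), "reactions")
  if (!is.null(object@meta$condition))
    cat(" (condition:", object@meta$condition, ")")
  cat("\n")
})

setMethod("show", "ScenarioResult", function(object) {
  cat("ScenarioResult:", nrow(object@steps), "steps; breakpoint carbon =",
      format(object@breakpointCarbon), ", C/N =",
      format(object@breakpointCNRatio), "\n")
})
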