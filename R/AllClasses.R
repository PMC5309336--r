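#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a constraint-based metabolic network
#'
#' Container for a stoichiometric model: metabolites, reactions with flux
#' bounds and gene-protein-reaction (GPR) associations, the stoichiometric
#' matrix S (metabolites x reactions), and the id of the biomass objective
#' reaction. Uptake is encoded as negative exchange flux, secretion as
#' positive, so forced uptake of u mM appears as bounds `[-u, -u]`.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`.
#' @slot reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `reversible`, `gpr`, `subsystem`.
#' @slot stoichiometry sparse `dgCMatrix`, rows named by metabolite id,
#'   columns by reaction id; entry is the signed stoichiometric coefficient.
#' @slot objective character(1), reaction id of the biomass objective.
#'
#' @seealso [loadModel()], [makeToyModel()], [applyConstraints()]
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  slots = c(
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "dgCMatrix",
    objective     = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  m <- object@metabolites; r <- object@reactions; S <- object@stoichiometry
  msgs <- character()
  need_m <- c("id", "name", "compartment")
  need_r <- c("id", "lower_bound", "upper_bound", "reversible", "gpr", "subsystem")
  if (!all(need_m %in% names(m))) msgs <- c(msgs, "metabolite table misses required columns")
  if (!all(need_r %in% names(r))) msgs <- c(msgs, "reaction table misses required columns")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(m$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(r$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (any(!nzchar(m$compartment))) msgs <- c(msgs, "empty metabolite compartment")
  if (nrow(S) != nrow(m) || ncol(S) != nrow(r))
    msgs <- c(msgs, "stoichiometric matrix dimensions do not match tables")
  else {
    if (!identical(rownames(S), m$id)) msgs <- c(msgs, "S rownames != metabolite ids")
    if (!identical(colnames(S), r$id)) msgs <- c(msgs, "S colnames != reaction ids")
  }
  if (any(r$lower_bound > r$upper_bound + 1e-12))
    msgs <- c(msgs, "reaction with lower_bound > upper_bound")
  if (length(object@objective) != 1L || is.na(object@objective) ||
      !(object@objective %in% r$id))
    msgs <- c(msgs, "objective does not resolve to a reaction id")
  if (length(msgs)) msgs else TRUE
})

#' FluxSolution: the result of one linear-programming solve
#'
#' @slot objectiveValue numeric(1); `NA` unless status is "optimal".
#' @slot fluxes named numeric vector of reaction fluxes (empty unless optimal).
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @exportClass FluxSolution
setClass("FluxSolution",
  slots = c(objectiveValue = "numeric", fluxes = "numeric", status = "character")
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal/infeasible/unbounded")
  TRUE
})

#' FluxSampleSet: flux vectors sampled from one condition's solution space
#'
#' @slot samples numeric matrix, one row per sampled flux vector, columns
#'   named by reaction id.
#' @slot meta list with at least `seed`, `n_points`, `step_count`,
#'   `condition`.
#' @seealso [sampleFluxes()], [validateSamples()], [testFluxShifts()]
#' @exportClass FluxSampleSet
setClass("FluxSampleSet",
  slots = c(samples = "matrix", meta = "list")
)

setValidity("FluxSampleSet", function(object) {
  s <- object@samples
  if (!is.numeric(s)) return("samples must be numeric")
  if (is.null(colnames(s)) || anyDuplicated(colnames(s)))
    return("samples must have unique reaction-id column names")
  if (nrow(s) < 2L) return("a sample set needs at least 2 rows")
  TRUE
})

#' ScenarioSpec: a carbon/nitrogen limitation scenario
#'
#' Describes a stepwise sweep of forced bicarbonate uptake with a nitrate
#' rule (constant, or ramped once carbon uptake passes a threshold) and the
#' set of storage/release demand reactions left open or closed.
#'
#' @slot scenario label, one of "s1", "s2", "s3", "cn_sweep".
#' @slot carbonRxn,nitrogenRxn exchange reaction ids for HCO3 and NO3.
#' @slot carbonGrid strictly increasing uptake magnitudes (mM).
#' @slot nitrogenBase constant nitrate uptake magnitude (mM).
#' @slot nitrogenRule "constant" or "ramp_after_threshold".
#' @slot rampThreshold,rampStep carbon level (mM) at which the nitrate ramp
#'   starts and its per-step increment; used only under the ramp rule.
#' @slot openDemands,closedDemands demand reaction ids opened to `[0, 1000]`
#'   or pinned to `[0, 0]` before each solve.
#' @seealso [scenarioSpec()], [runScenario()]
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  slots = c(
    scenario = "character", carbonRxn = "character", nitrogenRxn = "character",
    carbonGrid = "numeric", nitrogenBase = "numeric", nitrogenRule = "character",
    rampThreshold = "numeric", rampStep = "numeric",
    openDemands = "character", closedDemands = "character"
  )
)

setValidity("ScenarioSpec", function(object) {
  msgs <- character()
  if (!object@scenario %in% c("s1", "s2", "s3", "cn_sweep"))
    msgs <- c(msgs, "unknown scenario label")
  if (length(object@carbonGrid) < 1L || any(diff(object@carbonGrid) <= 0))
    msgs <- c(msgs, "carbonGrid must be non-empty and strictly increasing")
  if (!object@nitrogenRule %in% c("constant", "ramp_after_threshold"))
    msgs <- c(msgs, "nitrogenRule must be constant or ramp_after_threshold")
  if (object@nitrogenRule == "ramp_after_threshold" &&
      (!is.finite(object@rampThreshold) || !is.finite(object@rampStep)))
    msgs <- c(msgs, "ramp rule requires finite rampThreshold and rampStep")
  if (length(msgs)) msgs else TRUE
})

#' ScenarioResult: per-step fluxes and the detected limitation breakpoint
#'
#' @slot steps data.frame with one row per grid point: forced carbon and
#'   nitrogen uptake, biomass flux, the flux of every tracked demand
#'   reaction, and the C/N ratio.
#' @slot breakpointCarbon smallest carbon uptake at which biomass stops
#'   increasing (`NA` if the sweep never flattens).
#' @slot breakpointCNRatio `breakpointCarbon` divided by the nitrogen uptake
#'   at the breakpoint (`NA` if no breakpoint).
#' @exportClass ScenarioResult
setClass("ScenarioResult",
  slots = c(steps = "data.frame", breakpointCarbon = "numeric",
            breakpointCNRatio = "numeric")
)

#' CategoryMap: subsystem to macro-category and display-group lookup
#'
#' Maps each model subsystem to zero or more macro-categories ("carbon",
#' "nitrogen") and to exactly one of the nine display groups (amino acid,
#' carbon, cofactor, energy, glycan, lipid, nucleotide, pigments, transport)
#' or "unmapped".
#'
#' @slot macro named list: subsystem -> character vector drawn from
#'   `c("carbon", "nitrogen")` (possibly empty).
#' @slot display named character: subsystem -> display group.
#' @seealso [buildCategoryMap()]
#' @exportClass CategoryMap
setClass("CategoryMap",
  slots = c(macro = "list", display = "character")
)

setValidity("CategoryMap", function(object) {
  if (!identical(sort(names(object@macro)), sort(names(object@display))))
    return("macro and display must cover the same subsystems")
  bad <- vapply(object@macro, function(x) any(!x %in% c("carbon", "nitrogen")),
                logical(1))
  if (any(bad)) return("macro categories must be 'carbon'/'nitrogen'")
  TRUE
})
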