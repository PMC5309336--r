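# internal: solve max/min of a linear objective over {v : S v = 0, lb<=v<=ub}
solveModelLP <- function(model, obj, maximize = TRUE, solver = simplexSolver) {
  S <- as.matrix(model@stoichiometry)
  solver(obj, S, rep(0, nrow(S)), model@reactions$lower_bound,
         model@reactions$upper_bound, maximize = maximize)
}

objVector <- function(model, rxnId = model@objective) {
  obj <- numeric(nReactions(model))
  obj[match(rxnId, reactionIds(model))] <- 1
  obj
}

#' Flux balance analysis: maximise the biomass objective
#'
#' Maximises the flux of the model's objective reaction subject to the
#' steady-state constraint `S v = 0` and the flux bounds. Infeasible or
#' unbounded constraint sets are reported through the solution `status`,
#' not as errors.
#'
#' @param model a [MetabolicModel-class].
#' @param solver LP backend; see [simplexSolver()] for the contract.
#' @return a [FluxSolution-class].
#' @examples
#' toy <- makeToyModel()
#' toy <- applyConstraints(toy, constraintSet(
#'   c("EX_hco3_e", "EX_no3_e"), c(-1.2, -0.5), c(-1.2, -0.5)))
#' optimizeModel(toy)   # carbon-limited: biomass 1.2/6 = 0.2
#' @export
optimizeModel <- function(model, solver = simplexSolver) {
  stopifnot(is(model, "MetabolicModel"))
  res <- solveModelLP(model, objVector(model), maximize = TRUE, solver = solver)
  if (res$status != "optimal")
    return(new("FluxSolution", objectiveValue = NA_real_,
               fluxes = numeric(0), status = res$status))
  new("FluxSolution", objectiveValue = res$objective,
      fluxes = setNames(res$x, reactionIds(model)), status = "optimal")
}

#' Parsimonious FBA: a unique representative optimum
#'
#' Fixes the biomass flux at its optimum and then minimises the sum of
#' absolute fluxes, the standard tie-break that picks one enzymatically
#' frugal solution out of the space of alternate optima. Used wherever a
#' single flux vector per condition is reported (e.g. scenario sweeps).
#'
#' @inheritParams optimizeModel
#' @return a [FluxSolution-class]; its `objectiveValue` is the biomass flux
#'   (identical to [optimizeModel()]'s within solver tolerance), its fluxes
#'   the minimal-total-flux optimum.
#' @export
parsimoniousFBA <- function(model, solver = simplexSolver) {
  fba <- optimizeModel(model, solver = solver)
  if (fba@status != "optimal") return(fba)
  n <- nReactions(model)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  oj <- match(model@objective, reactionIds(model))
  lb[oj] <- fba@objectiveValue; ub[oj] <- fba@objectiveValue
  # split v = p - m, p, m >= 0; minimise sum(p + m)
  S <- as.matrix(model@stoichiometry)
  S2 <- cbind(S, -S)
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  res <- solver(rep(1, 2 * n), S2, rep(0, nrow(S)), lo, hi, maximize = FALSE)
  if (res$status != "optimal")
    return(new("FluxSolution", objectiveValue = NA_real_,
               fluxes = numeric(0), status = res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  new("FluxSolution", objectiveValue = fba@objectiveValue,
      fluxes = setNames(v, reactionIds(model)), status = "optimal")
}

#' Flux variability analysis
#'
#' Per reaction, the minimum and maximum flux achievable under the model's
#' constraints, optionally with the objective pinned at a fraction of its
#' optimum. `fixObjectiveFraction = 0` is pure feasibility FVA, the mode
#' used by [pruneBlocked()].
#'
#' @inheritParams optimizeModel
#' @param rxnIds reactions to analyse (default: all).
#' @param fixObjectiveFraction in `[0, 1]`; 0 leaves the objective free.
#' @return data.frame with columns `reaction_id`, `v_min`, `v_max`.
#' @export
fluxVariability <- function(model, rxnIds = reactionIds(model),
                            fixObjectiveFraction = 0,
                            solver = simplexSolver) {
  stopifnot(fixObjectiveFraction >= 0, fixObjectiveFraction <= 1)
  unknown <- setdiff(rxnIds, reactionIds(model))
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  if (fixObjectiveFraction > 0) {
    fba <- optimizeModel(model, solver = solver)
    if (fba@status != "optimal")
      stop("model is ", fba@status, "; cannot run FVA")
    oj <- match(model@objective, reactionIds(model))
    model@reactions$lower_bound[oj] <- fixObjectiveFraction * fba@objectiveValue
  }
  out <- lapply(rxnIds, function(r) {
    obj <- objVector(model, r)
    mn <- solveModelLP(model, obj, maximize = FALSE, solver = solver)
    mx <- solveModelLP(model, obj, maximize = TRUE, solver = solver)
    if (mn$status != "optimal" || mx$status != "optimal")
      stop("FVA solve failed for '", r, "' (status ",
           mn$status, "/", mx$status, ")")
    data.frame(reaction_id = r, v_min = mn$objective, v_max = mx$objective,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Remove blocked reactions and orphaned metabolites
#'
#' A reaction is blocked when feasibility FVA confines its flux to
#' `[-tol, tol]`; such reactions cannot carry flux under the applied
#' constraints and are removed together with metabolites left out of every
#' remaining reaction. The reduced model preserves feasibility and the
#' optimal objective value. Pruning an already-pruned model removes
#' nothing.
#'
#' @inheritParams optimizeModel
#' @param tol blocked-flux tolerance; defaults to the solver-noise floor.
#' @return list with elements `model` (the reduced [MetabolicModel-class]),
#'   `removedReactions`, `removedMetabolites`.
#' @export
pruneBlocked <- function(model, tol = 1e-9, solver = simplexSolver) {
  fva <- fluxVariability(model, fixObjectiveFraction = 0, solver = solver)
  blocked <- fva$reaction_id[abs(fva$v_min) <= tol & abs(fva$v_max) <= tol]
  blocked <- setdiff(blocked, model@objective)
  keep <- !(model@reactions$id %in% blocked)
  S <- model@stoichiometry[, keep, drop = FALSE]
  orphan <- Matrix::rowSums(S != 0) == 0
  model@reactions <- model@reactions[keep, , drop = FALSE]
  rownames(model@reactions) <- NULL
  removedMets <- rownames(S)[orphan]
  model@metabolites <- model@metabolites[!orphan, , drop = FALSE]
  rownames(model@metabolites) <- NULL
  model@stoichiometry <- S[!orphan, , drop = FALSE]
  validObject(model)
  list(model = model, removedReactions = blocked,
       removedMetabolites = removedMets)
}
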