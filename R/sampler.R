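# orthonormal basis of the null space of S (right singular vectors with
# negligible singular values); sampling directions live in this subspace
nullSpaceBasis <- function(S, tol = 1e-10) {
  S <- as.matrix(S)
  sv <- svd(S, nu = 0, nv = ncol(S))
  keep <- c(sv$d, rep(0, ncol(S) - length(sv$d))) <= tol * max(1, sv$d[1])
  sv$v[, keep, drop = FALSE]
}

#' Warmup points for hit-and-run sampling
#'
#' Generates the FVA-extreme flux vectors (for every reaction, the full
#' solutions of its flux minimisation and maximisation) plus their
#' centroid. All points satisfy `S v = 0` and the bounds, and the centroid
#' is strictly interior in every non-fixed coordinate, which is what the
#' chord-stepping chain needs to start mixing.
#'
#' @param model a feasible, preferably pruned [MetabolicModel-class].
#' @param seed integer; the warmup itself is deterministic but the seed is
#'   recorded for provenance.
#' @param solver LP backend.
#' @return list with `points` (2 x n_reactions rows, one flux vector each)
#'   and `center` (their centroid).
#' @export
generateWarmup <- function(model, seed = 1L, solver = simplexSolver) {
  rxns <- reactionIds(model)
  pts <- matrix(NA_real_, nrow = 2L * length(rxns), ncol = length(rxns),
                dimnames = list(NULL, rxns))
  k <- 0L
  for (r in rxns) {
    obj <- objVector(model, r)
    for (maximize in c(FALSE, TRUE)) {
      res <- solveModelLP(model, obj, maximize = maximize, solver = solver)
      if (res$status != "optimal")
        stop("warmup LP for '", r, "' is ", res$status)
      k <- k + 1L
      pts[k, ] <- res$x
    }
  }
  list(points = pts, center = colMeans(pts), seed = as.integer(seed))
}

#' Sample the steady-state flux polytope (artificially-centered hit-and-run)
#'
#' Uniform sampling of `{v : S v = 0, lb <= v <= ub}`. Starting from the
#' warmup centroid, each step draws a direction from the current point
#' towards a random warmup point re-centered on the running centroid
#' (the "artificially centered" direction set, which mixes well on the
#' elongated polytopes flux cones produce), finds the feasible chord along
#' that direction, and jumps to a uniform point on it. Every `thinning`-th
#' point is retained, with `thinning = ceiling(stepCount / nPoints)`, so a
#' published mixing parameter like "step count = 2 x reactions" maps onto
#' the chain length. Directions stay inside the null space of S by
#' construction; tiny numerical drift is clipped against the bounds and the
#' point is re-projected onto the null space at regular intervals.
#'
#' @param model a feasible, pruned [MetabolicModel-class].
#' @param nPoints number of samples to return.
#' @param stepCount total mixing parameter (hit-and-run steps across the
#'   whole chain); defaults to `2 * nReactions(model)`.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param condition free-text label stored in the metadata.
#' @param solver LP backend for the warmup stage.
#' @return a [FluxSampleSet-class].
#' @examples
#' toy <- makeToyModel()
#' toy <- applyConstraints(toy, constraintSet(
#'   c("EX_hco3_e", "EX_no3_e"), c(-3, -0.5), c(-3, -0.5)))
#' fs <- sampleFluxes(pruneBlocked(toy)$model, nPoints = 100, seed = 1)
#' validateSamples(pruneBlocked(toy)$model, fs)$nOffending  # 0
#' @export
sampleFluxes <- function(model, nPoints = 2000L,
                         stepCount = 2L * nReactions(model),
                         seed = 1L, condition = "default",
                         solver = simplexSolver) {
  stopifnot(nPoints >= 1L, stepCount >= 1L)
  wu <- generateWarmup(model, seed = seed, solver = solver)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  NB <- nullSpaceBasis(model@stoichiometry)
  thinning <- max(1L, as.integer(ceiling(stepCount / nPoints)))
  set.seed(as.integer(seed))
  W <- wu$points
  x <- wu$center
  center <- wu$center
  nSeen <- nrow(W)
  out <- matrix(NA_real_, nrow = nPoints, ncol = length(lb),
                dimnames = list(NULL, reactionIds(model)))
  kept <- 0L; stepsSinceProj <- 0L
  while (kept < nPoints) {
    for (s in seq_len(thinning)) {
      d <- W[sample.int(nrow(W), 1L), ] - center
      nd <- sqrt(sum(d * d))
      if (nd < 1e-12) next
      d <- d / nd
      # feasible chord: x + a*d within bounds
      aLo <- -Inf; aHi <- Inf
      for (i in which(abs(d) > 1e-11)) {
        r1 <- (lb[i] - x[i]) / d[i]; r2 <- (ub[i] - x[i]) / d[i]
        aLo <- max(aLo, min(r1, r2)); aHi <- min(aHi, max(r1, r2))
      }
      if (!is.finite(aLo) || !is.finite(aHi) || aHi <= aLo) next
      x <- x + runif(1L, aLo, aHi) * d
      stepsSinceProj <- stepsSinceProj + 1L
      if (stepsSinceProj >= 50L) {       # guard against drift off S v = 0
        x <- as.vector(NB %*% crossprod(NB, x))
        stepsSinceProj <- 0L
      }
      # clip solver-noise bound violations
      over <- x > ub; under <- x < lb
      if (any(c(x[over] - ub[over], lb[under] - x[under]) > 1e-9))
        x <- pmin(pmax(x, lb), ub)       # re-projection onto the box
      x[over] <- ub[over]; x[under] <- lb[under]
      center <- (center * nSeen + x) / (nSeen + 1)
      nSeen <- nSeen + 1
    }
    kept <- kept + 1L
    out[kept, ] <- x
  }
  new("FluxSampleSet", samples = out,
      meta = list(seed = as.integer(seed), n_points = as.integer(nPoints),
                  step_count = as.integer(stepCount), thinning = thinning,
                  condition = condition))
}

#' Validate a flux sample set against a model
#'
#' Reports (never throws) the worst mass-balance residual `max |S v|`, the
#' worst bound violation, and which rows exceed the stated tolerances.
#'
#' @param model a [MetabolicModel-class].
#' @param fss a [FluxSampleSet-class] over the same reactions.
#' @param tolSS steady-state residual tolerance.
#' @param tolBounds bound-violation tolerance.
#' @return list: `nSamples`, `maxResidual`, `maxBoundViolation`,
#'   `nOffending`, `offendingRows`.
#' @export
validateSamples <- function(model, fss, tolSS = 1e-6, tolBounds = 1e-9) {
  M <- if (is(fss, "FluxSampleSet")) samples(fss) else as.matrix(fss)
  if (nrow(M) == 0L)
    return(list(nSamples = 0L, maxResidual = 0, maxBoundViolation = 0,
                nOffending = 0L, offendingRows = integer(0)))
  idx <- match(colnames(M), reactionIds(model))
  if (anyNA(idx)) stop("sample columns not in model: ",
                       paste(colnames(M)[is.na(idx)], collapse = ", "))
  S <- as.matrix(model@stoichiometry)[, idx, drop = FALSE]
  resid <- abs(tcrossprod(M, S))
  lb <- model@reactions$lower_bound[idx]
  ub <- model@reactions$upper_bound[idx]
  viol <- pmax(sweep(M, 2, ub, `-`), 0) + pmax(sweep(-M, 2, -lb, `-`), 0)
  rowBad <- apply(resid, 1, max) > tolSS | apply(viol, 1, max) > tolBounds
  list(nSamples = nrow(M), maxResidual = max(resid),
       maxBoundViolation = max(viol), nOffending = sum(rowBad),
       offendingRows = which(rowBad))
}
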