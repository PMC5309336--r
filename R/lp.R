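#' Bounded-variable linear programming by the two-phase revised simplex
#'
#' Solves `min/max c'x` subject to `A x = b` and `lb <= x <= ub`. This is
#' the package's LP core behind [optimizeModel()], [fluxVariability()] and
#' [parsimoniousFBA()]. Bland's anti-cycling rule keeps the method finite on
#' the degenerate instances that flux variability analysis produces; basic
#' values are refreshed from the basis factorisation at every iteration so
#' rounding does not accumulate over a sweep.
#'
#' Any replacement solver with the same signature and return contract can be
#' passed to the FBA entry points through their `solver` argument.
#'
#' @param obj objective coefficients, length `ncol(A)`.
#' @param A dense or sparse constraint matrix of the equality system.
#' @param b right-hand side, length `nrow(A)`.
#' @param lb,ub variable bounds; at most one of the two may be infinite per
#'   variable.
#' @param maximize maximize instead of minimize.
#' @param tol reduced-cost/pivot tolerance.
#' @param maxIter iteration cap (phase 1 + phase 2 combined).
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   and for optimal solves `x` (the solution) and `objective`.
#' @examples
#' # max x1 + x2 s.t. x1 - x2 = 0, 0 <= x <= 1  -> (1, 1)
#' simplexSolver(c(1, 1), matrix(c(1, -1), 1), 0, c(0, 0), c(1, 1),
#'               maximize = TRUE)
#' @export
simplexSolver <- function(obj, A, b, lb, ub, maximize = FALSE,
                          tol = 1e-9, maxIter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))
  if (any(!is.finite(lb) & !is.finite(ub)))
    stop("variables free in both directions are not supported")
  cc <- if (maximize) -obj else obj

  N <- n + m
  cl <- c(lb, rep(0, m)); cu <- c(ub, rep(Inf, m))
  # structural variables start nonbasic at their finite bound of smaller size
  useLower <- is.finite(lb) & (!is.finite(ub) | abs(lb) <= abs(ub))
  atUpper <- logical(N)
  atUpper[seq_len(n)] <- !useLower
  xval <- numeric(N)
  xval[seq_len(n)] <- ifelse(useLower, lb, ub)
  resid <- b - as.vector(A %*% xval[seq_len(n)])
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  basis <- (n + 1L):N
  nonbasic <- seq_len(n)
  xval[basis] <- abs(resid)
  phase <- 1L
  cost <- c(rep(0, n), rep(1, m))

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter) stop("simplex iteration limit reached")
    B <- Afull[, basis, drop = FALSE]
    xb <- tryCatch(
      solve(B, b - Afull[, nonbasic, drop = FALSE] %*% xval[nonbasic]),
      error = function(e) NULL)
    if (is.null(xb)) stop("singular basis encountered in simplex")
    xval[basis] <- as.vector(xb)
    y <- solve(t(B), cost[basis])
    dN <- cost[nonbasic] - as.vector(crossprod(Afull[, nonbasic, drop = FALSE], y))
    elig <- (!atUpper[nonbasic] & dN < -tol) | (atUpper[nonbasic] & dN > tol)
    if (!any(elig)) {
      if (phase == 1L) {
        if (sum(cost * xval) > 1e-7) return(list(status = "infeasible"))
        cl[(n + 1L):N] <- 0; cu[(n + 1L):N] <- 0     # pin artificials
        xval[(n + 1L):N][xval[(n + 1L):N] < 0] <- 0
        cost <- c(cc, rep(0, m))
        phase <- 2L
        next
      }
      x <- xval[seq_len(n)]
      val <- sum(obj * x)
      return(list(status = "optimal", x = x, objective = val))
    }
    j <- min(nonbasic[elig])                          # Bland's rule
    s <- if (atUpper[j]) -1 else 1
    w <- as.vector(solve(B, Afull[, j]))
    tlim <- cu[j] - cl[j]                             # bound-to-bound flip
    leave <- 0L; leaveToUpper <- FALSE
    for (k in seq_len(m)) {
      wk <- s * w[k]
      bi <- basis[k]
      if (wk > tol) {
        lim <- (xval[bi] - cl[bi]) / wk
      } else if (wk < -tol) {
        if (!is.finite(cu[bi])) next
        lim <- (cu[bi] - xval[bi]) / (-wk)
      } else next
      lim <- max(lim, 0)
      if (lim < tlim - 1e-12 ||
          (lim < tlim + 1e-12 && (leave == 0L || bi < basis[leave]))) {
        tlim <- lim; leave <- k; leaveToUpper <- wk < 0
      }
    }
    if (!is.finite(tlim)) return(list(status = "unbounded"))
    xval[basis] <- xval[basis] - s * tlim * w
    xval[j] <- xval[j] + s * tlim
    if (leave == 0L) {
      atUpper[j] <- !atUpper[j]
    } else {
      lv <- basis[leave]
      xval[lv] <- if (leaveToUpper) cu[lv] else cl[lv]
      atUpper[lv] <- leaveToUpper
      basis[leave] <- j
      nonbasic <- sort(c(nonbasic[nonbasic != j], lv))
    }
  }
}
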