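# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Benjamini-Hochberg step-up, written out from the definition:
# q_(i) = min_{j >= i} ( N * p_(j) / j ), capped at 1, on the sorted scale.
bhOracle <- function(p) {
  N <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, N * ps / seq_len(N))
  q <- rev(cummin(rev(q)))
  out <- numeric(N)
  out[o] <- q
  out
}

# exact hypergeometric tails by direct summation of the pmf
hyperOverOracle <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(stats::dhyper(j, K, N - K, n))
}
hyperUnderOracle <- function(k, K, n, N) {
  j <- 0:k
  sum(stats::dhyper(j, K, N - K, n))
}

# brute-force all-pairs Jaccard edge set
jaccardEdgesOracle <- function(sets, threshold) {
  ids <- names(sets)
  out <- list()
  if (length(ids) < 2) return(matrix(character(0), ncol = 2))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- sets[[i]]; b <- sets[[j]]
    u <- length(union(a, b))
    sc <- if (u == 0) 0 else length(intersect(a, b)) / u
    if (sc > threshold) out[[length(out) + 1]] <- c(ids[i], ids[j])
  }
  if (length(out)) do.call(rbind, out) else matrix(character(0), ncol = 2)
}

# closed-form toy growth: biomass = min(carbon/cPerB, nitrogen/nPerB)
toyGrowthOracle <- function(uc, un, cPerB = 6, nPerB = 1) {
  min(uc / cPerB, un / nPerB)
}

# toy model with forced uptakes and a chosen set of open demands
toyAt <- function(uc, un, open = c("DM_dmsp_c", "DM_no3_c"),
                  model = makeToyModel()) {
  allDm <- c("DM_dmsp_c", "DM_no3_c", "DM_tag_c", "DM_chryso_c")
  closed <- setdiff(allDm, open)
  cs <- constraintSet(
    c("EX_hco3_e", "EX_no3_e", open, closed),
    c(-uc, -un, rep(0, length(open)), rep(0, length(closed))),
    c(-uc, -un, rep(1000, length(open)), rep(0, length(closed))))
  applyConstraints(model, cs)
}

# tiny polytopes with known geometry for sampler cross-checks --------------

# one metabolite, two opposed exchanges: v2 = -v1, v1 uniform on [-1, 1]
segmentModel <- function() {
  mets <- data.frame(id = "a_e", name = "a", compartment = "e",
                     stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX1", stoichiometry = c(a_e = -1), lower_bound = -1,
         upper_bound = 1, reversible = TRUE, gpr = "", subsystem = ""),
    list(id = "EX2", stoichiometry = c(a_e = -1), lower_bound = -1,
         upper_bound = 1, reversible = TRUE, gpr = "", subsystem = ""))
  cnflux:::buildModel(mets, rxns, "EX1")
}

# three opposed exchanges: v1 + v2 + v3 = 0 inside [-1,1]^3 (a 2-D hexagon)
triModel <- function() {
  mets <- data.frame(id = "a_e", name = "a", compartment = "e",
                     stringsAsFactors = FALSE)
  rxns <- lapply(1:3, function(i)
    list(id = paste0("EX", i), stoichiometry = c(a_e = -1),
         lower_bound = -1, upper_bound = 1, reversible = TRUE,
         gpr = "", subsystem = ""))
  cnflux:::buildModel(mets, rxns, "EX1")
}

# rejection-sampling oracle on the same polytopes
rejectionSegment <- function(n, seed) {
  set.seed(seed)
  v1 <- runif(n, -1, 1)
  cbind(EX1 = v1, EX2 = -v1)
}
rejectionTri <- function(n, seed) {
  set.seed(seed)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    v1 <- runif(2 * n, -1, 1); v2 <- runif(2 * n, -1, 1)
    v3 <- -(v1 + v2)
    ok <- abs(v3) <= 1
    out <- rbind(out, cbind(v1[ok], v2[ok], v3[ok]))
  }
  out <- out[seq_len(n), ]
  colnames(out) <- c("EX1", "EX2", "EX3")
  out
}

# Monte-Carlo shift-test call with fresh normal vectors
simulateShiftP <- function(nRxns, n, delta, seed, nRepeats = 100) {
  set.seed(seed)
  vapply(seq_len(nRxns), function(i) {
    shiftStatistic(rnorm(n), rnorm(n, delta), nRepeats = nRepeats)$p_value
  }, numeric(1))
}
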