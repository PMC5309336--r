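#' Permutation histogram-distance statistic for two flux distributions
#'
#' Decides whether two equal-length samples of a reaction's flux (one per
#' condition) come from shifted distributions. Per repeat, both vectors are
#' independently permuted and subtracted elementwise; the minority sign
#' count of the difference vector (`min(#positive, #negative)`) measures
#' how much the histograms overlap: fully separated distributions give 0,
#' identical ones about n/2. The statistic is the mean minority count over
#' the repeats divided by n, and the two-sided p-value is `min(1, 2*stat)`.
#' Zero differences count toward neither sign; if the two vectors are
#' elementwise identical there is no evidence of any difference and the
#' degenerate p-value 1 is returned (with `stat = 0.5` so `p = 2*stat`
#' still holds).
#'
#' @param vLow,vHigh numeric vectors of equal length `n >= 2` (flux samples
#'   under the low- and high-carbon condition).
#' @param nRepeats number of permutation repeats (default 100).
#' @param seed optional integer seed for the permutations.
#' @return list with `stat` (in `[0, 0.5]`) and `p_value`.
#' @examples
#' shiftStatistic(rnorm(100), rnorm(100) + 5, seed = 1)$p_value  # 0
#' @export
shiftStatistic <- function(vLow, vHigh, nRepeats = 100L, seed = NULL) {
  n <- length(vLow)
  if (length(vHigh) != n) stop("vLow and vHigh must have equal length")
  if (n < 2L) stop("need at least 2 samples per condition")
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  if (all(vLow == vHigh)) return(list(stat = 0.5, p_value = 1))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mins <- vapply(seq_len(nRepeats), function(k) {
    d <- vLow[sample.int(n)] - vHigh[sample.int(n)]
    min(sum(d > 0), sum(d < 0))
  }, numeric(1))
  stat <- mean(mins) / n
  list(stat = stat, p_value = min(1, 2 * stat))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @return monotone adjusted q-values, each at least its p-value.
#' @export
bhAdjust <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Test every reaction for a flux-distribution shift between two conditions
#'
#' Applies [shiftStatistic()] to each reaction shared by the two sample
#' sets, adjusts across all tested reactions with Benjamini-Hochberg, and
#' flags significance at `alpha`. The shift direction is the sign of
#' `median(high) - median(low)` (median for robustness against the skewed
#' marginals flux sampling produces). Reactions present in only one set
#' are skipped and listed in the `skipped` attribute.
#'
#' @param low,high [FluxSampleSet-class] objects with a common reaction
#'   ordering and equal row counts (or a common `subsample`).
#' @param nRepeats permutation repeats per reaction.
#' @param alpha FDR significance threshold.
#' @param seed integer seed (one stream drives all reactions, so results
#'   are reproducible as a whole).
#' @param subsample optional row count: each condition is subsampled to
#'   this many rows (seeded) before testing, for very large sample sets.
#' @return data.frame with one row per tested reaction: `reaction_id`,
#'   `stat`, `p_value`, `q_value`, `direction` ("up"/"down"/"none"),
#'   `significant`; skipped reaction ids in `attr(, "skipped")`.
#' @export
testFluxShifts <- function(low, high, nRepeats = 100L, alpha = 0.05,
                           seed = 1L, subsample = NULL) {
  ML <- samples(low); MH <- samples(high)
  shared <- intersect(colnames(ML), colnames(MH))
  if (!length(shared)) stop("the two sample sets share no reactions")
  skipped <- union(setdiff(colnames(ML), shared), setdiff(colnames(MH), shared))
  set.seed(as.integer(seed))
  if (!is.null(subsample)) {
    ML <- ML[sample.int(nrow(ML), min(subsample, nrow(ML))), , drop = FALSE]
    MH <- MH[sample.int(nrow(MH), min(subsample, nrow(MH))), , drop = FALSE]
  }
  if (nrow(ML) != nrow(MH))
    stop("conditions have different sample counts; use `subsample`")
  res <- lapply(shared, function(r) {
    st <- shiftStatistic(ML[, r], MH[, r], nRepeats = nRepeats)
    dmed <- median(MH[, r]) - median(ML[, r])
    data.frame(reaction_id = r, stat = st$stat, p_value = st$p_value,
               direction = if (dmed > 0) "up" else if (dmed < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bhAdjust(out$p_value)
  out$significant <- out$q_value < alpha & out$direction != "none"
  out <- out[, c("reaction_id", "stat", "p_value", "q_value", "direction",
                 "significant")]
  attr(out, "skipped") <- skipped
  out
}

#' Summarise shifted reactions per display group
#'
#' Counts, per display group (amino acid, carbon, cofactor, energy, glycan,
#' lipid, nucleotide, pigments, transport), how many reactions shifted up
#' or down between the conditions, as percentages of all model reactions
#' in the group. With `geneAssociatedOnly` (the default), significant
#' reactions without a GPR are dropped before counting, since they cannot
#' be confronted with expression data.
#'
#' @param results output of [testFluxShifts()].
#' @param model the [MetabolicModel-class] the reactions belong to.
#' @param cmap a [CategoryMap-class] mapping subsystems to display groups.
#' @param geneAssociatedOnly drop significant reactions with empty GPRs.
#' @return data.frame: `group`, `n_reactions_in_group`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down`. Subsystems absent from the map are pooled into
#'   "unmapped" with a warning.
#' @export
summarizeGroups <- function(results, model, cmap, geneAssociatedOnly = TRUE) {
  unknown <- setdiff(results$reaction_id, reactionIds(model))
  if (length(unknown))
    stop("results contain reactions not in the model: ",
         paste(unknown, collapse = ", "))
  subs <- subsystems(model)
  grp <- cmap@display[subs]
  if (anyNA(grp)) {
    warning("subsystem(s) not in the category map, pooled as 'unmapped': ",
            paste(unique(subs[is.na(grp)]), collapse = ", "))
    grp[is.na(grp)] <- "unmapped"
  }
  names(grp) <- names(subs)
  sig <- results[results$significant, , drop = FALSE]
  if (geneAssociatedOnly) {
    gpr <- setNames(model@reactions$gpr, model@reactions$id)
    hasGene <- vapply(gpr[sig$reaction_id],
                      function(g) length(gprGenes(g)) > 0, logical(1))
    sig <- sig[hasGene, , drop = FALSE]
  }
  groups <- sort(unique(grp))
  out <- lapply(groups, function(g) {
    inGroup <- names(grp)[grp == g]
    nG <- length(inGroup)
    nUp <- sum(sig$reaction_id %in% inGroup & sig$direction == "up")
    nDown <- sum(sig$reaction_id %in% inGroup & sig$direction == "down")
    data.frame(group = g, n_reactions_in_group = nG, n_up = nUp,
               n_down = nDown, pct_up = 100 * nUp / nG,
               pct_down = 100 * nDown / nG, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare sampling hits with differentially expressed genes per subsystem
#'
#' Maps a differentially-expressed gene list onto reactions through the
#' GPRs and tabulates, per subsystem, how many reactions were flagged only
#' by flux-space sampling, only by differential expression, or by both.
#'
#' @param samplingHits reaction ids flagged by the flux shift test.
#' @param deGenes gene ids from an (external) differential expression
#'   analysis.
#' @param model a [MetabolicModel-class].
#' @return data.frame: `subsystem`, `n_sampling_only`, `n_de_only`,
#'   `n_shared`.
#' @export
compareHitSets <- function(samplingHits, deGenes, model) {
  deRxns <- unique(unlist(mapGenesToReactions(model, deGenes)))
  subs <- subsystems(model)
  touched <- union(samplingHits, deRxns)
  sysList <- sort(unique(subs[intersect(touched, names(subs))]))
  out <- lapply(sysList, function(ss) {
    inSys <- names(subs)[subs == ss]
    s <- intersect(samplingHits, inSys)
    d <- intersect(deRxns, inSys)
    data.frame(subsystem = ss,
               n_sampling_only = length(setdiff(s, d)),
               n_de_only = length(setdiff(d, s)),
               n_shared = length(intersect(s, d)),
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(subsystem = character(), n_sampling_only = integer(),
                      n_de_only = integer(), n_shared = integer()))
  do.call(rbind, out)
}
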