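#' Build the hand-solvable toy carbon/nitrogen model
#'
#' A two-compartment (extracellular `e`, cytosol `c`) network small enough
#' to solve by hand: bicarbonate and nitrate exchanges and transporters, a
#' carbon-fixation step (the bicarbonate transporter exports a proton that
#' carbon fixation re-consumes, so transport and fixation fluxes are
#' stoichiometrically locked), nitrate assimilation, a biomass objective
#' consuming `cPerBiomass` fixed carbons and `nPerBiomass` organic
#' nitrogens per unit growth, and four sinks: DMSP synthesis + release
#' (the only carbon-secretion route), a nitrate-storage demand, TAG
#' storage, and chrysolaminarin storage. Carbon bookkeeping is integer
#' (1 cfix = 1 fixed carbon) so conservation checks are exact:
#' at any solution, `cPerBiomass*biomass + dmspCarbons*DMSP +
#' tagCarbons*TAG + (chrysoCarbons+chrysoPenalty)*chrysolaminarin = carbon
#' uptake` and `nPerBiomass*biomass + nitrate_storage = nitrogen uptake`.
#'
#' The chrysolaminarin route carries a built-in extra-carbon penalty
#' (`chrysoPenalty > 0`) so that parsimonious solutions route excess carbon
#' through the TAG demand deterministically; this is a modelling choice to
#' make the storage preference reproducible, not a biological claim.
#'
#' Demand reactions not listed in `includeDemands` remain in the model but
#' closed to `[0, 0]`; with all carbon sinks closed, forcing carbon uptake
#' beyond the biomass breakpoint makes the model infeasible, as mass
#' balance requires.
#'
#' @param cPerBiomass,nPerBiomass carbons / nitrogens consumed per unit of
#'   biomass (defaults 6 and 1, so the limitation breakpoint sits at
#'   C/N = 6).
#' @param dmspCarbons carbons released per DMSP (default 5).
#' @param tagCarbons carbons stored per TAG (default 50).
#' @param chrysoCarbons,chrysoPenalty carbons per chrysolaminarin and the
#'   wasted extra carbons on that route (defaults 6 and 1).
#' @param includeDemands demand reactions left open by default.
#' @return a validated [MetabolicModel-class] with 14 reactions and 10
#'   metabolites; every reaction carries a one-gene GPR and a subsystem
#'   label.
#' @examples
#' toy <- makeToyModel()
#' toy
#' @export
makeToyModel <- function(cPerBiomass = 6, nPerBiomass = 1, dmspCarbons = 5,
                         tagCarbons = 50, chrysoCarbons = 6,
                         chrysoPenalty = 1,
                         includeDemands = c("DM_dmsp_c", "DM_no3_c",
                                            "DM_tag_c", "DM_chryso_c")) {
  stopifnot(cPerBiomass > 0, nPerBiomass > 0, dmspCarbons > 0,
            tagCarbons > 0, chrysoCarbons > 0, chrysoPenalty > 0)
  mets <- data.frame(
    id = c("hco3_e", "no3_e", "hco3_c", "no3_c", "h_c", "cfix_c",
           "orgN_c", "dmsp_c", "tag_c", "chryso_c"),
    name = c("bicarbonate", "nitrate", "bicarbonate", "nitrate", "proton",
             "fixed carbon", "organic nitrogen", "DMSP", "triacylglycerol",
             "chrysolaminarin"),
    compartment = c("e", "e", "c", "c", "c", "c", "c", "c", "c", "c"),
    stringsAsFactors = FALSE)
  dm <- function(id) if (id %in% includeDemands) 1000 else 0
  rxns <- list(
    list(id = "EX_hco3_e", stoichiometry = c(hco3_e = -1),
         lower_bound = -1000, upper_bound = 1000, reversible = TRUE,
         gpr = "gEXC", subsystem = "transport"),
    list(id = "EX_no3_e", stoichiometry = c(no3_e = -1),
         lower_bound = -1000, upper_bound = 1000, reversible = TRUE,
         gpr = "gEXN", subsystem = "transport"),
    list(id = "THCO3", stoichiometry = c(hco3_e = -1, hco3_c = 1, h_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "gTHCO3",
         subsystem = "transport"),
    list(id = "TNO3", stoichiometry = c(no3_e = -1, no3_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "gTNO3",
         subsystem = "transport"),
    list(id = "CFIX", stoichiometry = c(hco3_c = -1, h_c = -1, cfix_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "gCFIX",
         subsystem = "carbon fixation"),
    list(id = "NASM", stoichiometry = c(no3_c = -1, orgN_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "gNASM",
         subsystem = "nitrogen metabolism"),
    list(id = "BOF",
         stoichiometry = setNames(c(-cPerBiomass, -nPerBiomass),
                                  c("cfix_c", "orgN_c")),
         lower_bound = 0, upper_bound = 1000, gpr = "gBOF",
         subsystem = "biomass production"),
    list(id = "DMSPS", stoichiometry = setNames(c(-dmspCarbons, 1),
                                                c("cfix_c", "dmsp_c")),
         lower_bound = 0, upper_bound = 1000, gpr = "gDMSP",
         subsystem = "amino acid metabolism"),
    list(id = "DM_dmsp_c", stoichiometry = c(dmsp_c = -1),
         lower_bound = 0, upper_bound = dm("DM_dmsp_c"), gpr = "gDMSP",
         subsystem = "transport"),
    list(id = "DM_no3_c", stoichiometry = c(no3_c = -1),
         lower_bound = 0, upper_bound = dm("DM_no3_c"), gpr = "gNST",
         subsystem = "nitrogen metabolism"),
    list(id = "TAGS", stoichiometry = setNames(c(-tagCarbons, 1),
                                               c("cfix_c", "tag_c")),
         lower_bound = 0, upper_bound = 1000, gpr = "gTAG",
         subsystem = "lipid metabolism"),
    list(id = "DM_tag_c", stoichiometry = c(tag_c = -1),
         lower_bound = 0, upper_bound = dm("DM_tag_c"), gpr = "gTAG",
         subsystem = "lipid metabolism"),
    list(id = "CHRYS",
         stoichiometry = setNames(c(-(chrysoCarbons + chrysoPenalty), 1),
                                  c("cfix_c", "chryso_c")),
         lower_bound = 0, upper_bound = 1000, gpr = "gCHR",
         subsystem = "glycan metabolism"),
    list(id = "DM_chryso_c", stoichiometry = c(chryso_c = -1),
         lower_bound = 0, upper_bound = dm("DM_chryso_c"), gpr = "gCHR",
         subsystem = "glycan metabolism"))
  model <- buildModel(mets, rxns, "BOF")
  validObject(model)
  model
}

#' Planted flux-sample fixtures for the shift test
#'
#' Generates a low- and a high-condition sample matrix over
#' `nNull + nShifted` synthetic reactions. Null reactions draw both
#' conditions i.i.d. from the same distribution; shifted reactions draw
#' the high condition with its mean moved by `shiftSdUnits` standard
#' deviations. These matrices are distribution-level fixtures for the
#' permutation statistic and are intentionally *not* mass-balanced against
#' any model; feasibility of real sample sets is the sampler's concern.
#'
#' @param nNull,nShifted number of null / shifted reactions.
#' @param nSamples rows per condition (>= 10).
#' @param shiftSdUnits shift size in SD units.
#' @param baseDistribution "normal" or "lognormal".
#' @param seed integer seed; fixtures are pure functions of it.
#' @return list: `low` and `high` ([FluxSampleSet-class]) and `shifted`
#'   (ground-truth shifted reaction ids).
#' @export
makePlantedSamples <- function(nNull = 50L, nShifted = 10L, nSamples = 1000L,
                               shiftSdUnits = 2, baseDistribution = c("normal",
                                                                      "lognormal"),
                               seed = 1L) {
  baseDistribution <- match.arg(baseDistribution)
  stopifnot(nNull >= 0L, nShifted >= 0L, nSamples >= 10L)
  set.seed(as.integer(seed))
  nR <- nNull + nShifted
  ids <- c(sprintf("rxn_null_%02d", seq_len(nNull)),
           sprintf("rxn_shift_%02d", seq_len(nShifted)))
  mu <- runif(nR, -1, 1)
  sd <- runif(nR, 0.5, 1.5)
  draw <- function(m, s) {
    if (baseDistribution == "normal") rnorm(nSamples, m, s)
    else rlnorm(nSamples, m, s / 3)
  }
  low <- vapply(seq_len(nR), function(j) draw(mu[j], sd[j]),
                numeric(nSamples))
  shift <- c(rep(0, nNull), rep(shiftSdUnits, nShifted)) * sd
  high <- vapply(seq_len(nR), function(j) draw(mu[j] + shift[j], sd[j]),
                 numeric(nSamples))
  colnames(low) <- ids; colnames(high) <- ids
  meta <- function(cond) list(seed = as.integer(seed),
                              n_points = as.integer(nSamples),
                              step_count = NA_integer_, condition = cond)
  list(low = new("FluxSampleSet", samples = low, meta = meta("low")),
       high = new("FluxSampleSet", samples = high, meta = meta("high")),
       shifted = ids[seq_len(nShifted) + nNull])
}

#' Planted cluster fixtures with known connectivity and enrichment
#'
#' Augments a copy of the model with synthetic genes, reactions and
#' product metabolites so that the resulting clusters realise a requested
#' pairwise Jaccard overlap of their product sets (within about 0.01 at
#' the default set size), plants one enriched term per cluster in the
#' accompanying gene-term table, and returns the exact expected edges and
#' component sizes at the 0.9 connectivity threshold.
#'
#' Overlap is realised through blocks of metabolites shared by exactly one
#' cluster pair: for target Jaccard `t` and per-cluster set size
#' `setSize`, the pair shares `round(2*setSize*t/(1+t))` metabolites. A
#' cluster whose requested overlaps need more shared metabolites than
#' `setSize` is unrealisable and raises an error stating the limit.
#'
#' @param model a [MetabolicModel-class] to augment (copy; the input is
#'   untouched).
#' @param nClusters number of synthetic clusters.
#' @param overlapTargets symmetric numeric matrix (`nClusters^2`) of
#'   target Jaccard scores; default: no overlap.
#' @param enrichedTerms character vector, one planted term per cluster
#'   (recycled); default `term_01..`.
#' @param genesPerCluster genes per cluster; `annotatedPerCluster` of them
#'   carry the cluster's planted term.
#' @param setSize product metabolites per cluster.
#' @param bgAnnotated how many genes outside each planted cluster also
#'   carry its term (background noise for the enrichment test).
#' @param threshold connectivity threshold used for the returned ground
#'   truth.
#' @param seed integer seed.
#' @return list: `clusters` (named list cluster -> genes), `model` (the
#'   augmented [MetabolicModel-class]), `geneTerms` (named list gene ->
#'   terms), `productSets` (the planted metabolite sets), `edges`
#'   (two-column matrix of expected edges), `componentSizes` (decreasing),
#'   `plantedTerms` (named character: cluster -> its enriched term).
#' @export
makePlantedClusters <- function(model, nClusters = 8L,
                                overlapTargets = NULL,
                                enrichedTerms = NULL,
                                genesPerCluster = 10L,
                                annotatedPerCluster = 8L,
                                setSize = 100L, bgAnnotated = 4L,
                                threshold = 0.9, seed = 1L) {
  stopifnot(nClusters >= 1L, setSize >= 2L,
            annotatedPerCluster <= genesPerCluster)
  if (is.null(overlapTargets))
    overlapTargets <- matrix(0, nClusters, nClusters)
  stopifnot(nrow(overlapTargets) == nClusters,
            ncol(overlapTargets) == nClusters,
            all(abs(overlapTargets - Matrix::t(overlapTargets)) < 1e-12),
            all(overlapTargets >= 0 & overlapTargets <= 1))
  set.seed(as.integer(seed))
  clNames <- sprintf("cluster_%02d", seq_len(nClusters))
  if (is.null(enrichedTerms))
    enrichedTerms <- sprintf("term_%02d", seq_len(nClusters))
  enrichedTerms <- rep_len(enrichedTerms, nClusters)

  # shared-block sizes per pair
  shared <- matrix(0L, nClusters, nClusters)
  for (i in seq_len(nClusters)) for (j in seq_len(nClusters)) {
    if (j > i && overlapTargets[i, j] > 0) {
      tt <- overlapTargets[i, j]
      shared[i, j] <- as.integer(round(2 * setSize * tt / (1 + tt)))
    }
  }
  for (i in seq_len(nClusters)) {
    tot <- sum(shared[i, ]) + sum(shared[, i])
    if (tot > setSize)
      stop("unachievable overlap target: cluster ", clNames[i], " needs ",
           tot, " shared metabolites but sets hold only ", setSize)
  }
  metCounter <- 0L
  newMet <- function(k) {
    ids <- sprintf("synMet_%04d_c", metCounter + seq_len(k))
    metCounter <<- metCounter + k
    ids
  }
  sets <- replicate(nClusters, character(0), simplify = FALSE)
  for (i in seq_len(nClusters)) for (j in seq_len(nClusters)) {
    if (shared[i, j] > 0) {
      blk <- newMet(shared[i, j])
      sets[[i]] <- c(sets[[i]], blk); sets[[j]] <- c(sets[[j]], blk)
    }
  }
  for (i in seq_len(nClusters))
    sets[[i]] <- c(sets[[i]], newMet(setSize - length(sets[[i]])))
  names(sets) <- clNames

  # genes, clusters, terms
  clusters <- lapply(seq_len(nClusters), function(i)
    sprintf("gSyn_%02d_%02d", i, seq_len(genesPerCluster)))
  names(clusters) <- clNames
  allGenes <- unlist(clusters)
  geneTerms <- setNames(vector("list", length(allGenes)), allGenes)
  for (i in seq_len(nClusters)) {
    carriers <- clusters[[i]][seq_len(annotatedPerCluster)]
    outsiders <- sample(setdiff(allGenes, clusters[[i]]),
                        min(bgAnnotated, length(allGenes) - genesPerCluster))
    for (g in c(carriers, outsiders))
      geneTerms[[g]] <- unique(c(geneTerms[[g]], enrichedTerms[i]))
  }

  # augment the model: per cluster one irreversible synthetic reaction
  # producing its metabolite set, GPR = "or" over the cluster's genes
  allMets <- sprintf("synMet_%04d_c", seq_len(metCounter))
  srcMets <- sprintf("synSrc_%02d_c", seq_len(nClusters))
  mets2 <- rbind(model@metabolites,
                 data.frame(id = c(allMets, srcMets),
                            name = c(allMets, srcMets),
                            compartment = "c", stringsAsFactors = FALSE))
  oldRxns <- lapply(seq_len(nReactions(model)), function(j) {
    col <- model@stoichiometry[, j]
    r <- model@reactions[j, ]
    list(id = r$id, stoichiometry = col[col != 0],
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         reversible = r$reversible, gpr = r$gpr, subsystem = r$subsystem)
  })
  synRxns <- lapply(seq_len(nClusters), function(i) {
    st <- setNames(c(-1, rep(1, length(sets[[i]]))),
                   c(srcMets[i], sets[[i]]))
    list(id = sprintf("SYNR_%02d", i), stoichiometry = st,
         lower_bound = 0, upper_bound = 0,
         gpr = paste(clusters[[i]], collapse = " or "),
         subsystem = "synthetic cluster reaction")
  })
  model2 <- buildModel(mets2, c(oldRxns, synRxns), model@objective)
  validObject(model2)

  # ground-truth edges/components from the realised sets
  jac <- function(a, b) {
    u <- length(union(a, b)); if (u == 0L) 0 else length(intersect(a, b)) / u
  }
  edges <- list()
  if (nClusters >= 2L)
    for (pair in utils::combn(nClusters, 2, simplify = FALSE))
      if (jac(sets[[pair[1]]], sets[[pair[2]]]) > threshold)
        edges[[length(edges) + 1L]] <- clNames[pair]
  edgeMat <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edgeMat, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = clNames))
  compSizes <- sort(unname(igraph::components(g)$csize), decreasing = TRUE)

  list(clusters = clusters, model = model2, geneTerms = geneTerms,
       productSets = sets, edges = edgeMat, componentSizes = compSizes,
       plantedTerms = setNames(enrichedTerms, clNames))
}
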