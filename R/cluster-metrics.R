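# canonical subsystem lists behind the carbon/nitrogen categorisation
NITROGEN_SUBSYSTEMS <- c("amino acid metabolism", "nitrogen metabolism",
                         "nucleotide metabolism", "urea cycle")
CARBON_SUBSYSTEMS <- c("aldehyde degradation", "ascorbate metabolism",
                       "butanoate metabolism", "calvin-benson cycle",
                       "carbon fixation", "galactose metabolism",
                       "nucleotide sugar metabolism",
                       "oxidative phosphorylation", "photosynthesis",
                       "pentose interconversions", "pentose phosphate pathway",
                       "pyruvate metabolism")
BOTH_SUBSYSTEMS <- "tricarboxylic acid cycle"

DEFAULT_DISPLAY_GROUPS <- c(
  "amino acid metabolism" = "amino acid", "nitrogen metabolism" = "amino acid",
  "urea cycle" = "amino acid", "nucleotide metabolism" = "nucleotide",
  "nucleotide sugar metabolism" = "carbon",
  "aldehyde degradation" = "carbon", "ascorbate metabolism" = "carbon",
  "butanoate metabolism" = "carbon", "calvin-benson cycle" = "carbon",
  "carbon fixation" = "carbon", "galactose metabolism" = "carbon",
  "pentose interconversions" = "carbon", "pentose phosphate pathway" = "carbon",
  "pyruvate metabolism" = "carbon", "tricarboxylic acid cycle" = "carbon",
  "oxidative phosphorylation" = "energy", "photosynthesis" = "energy",
  "glycolysis/gluconeogenesis" = "carbon",
  "lipid metabolism" = "lipid", "glycan metabolism" = "glycan",
  "cofactor metabolism" = "cofactor", "pigment biosynthesis" = "pigments",
  "pigment metabolism" = "pigments", "transport" = "transport")

#' Build the subsystem-to-category map
#'
#' Assigns each subsystem zero or more macro-categories: amino acid
#' metabolism, nitrogen metabolism, nucleotide metabolism and the urea
#' cycle are nitrogen; aldehyde degradation, ascorbate metabolism,
#' butanoate metabolism, the Calvin-Benson cycle, carbon fixation,
#' galactose metabolism, nucleotide sugar metabolism, oxidative
#' phosphorylation, photosynthesis, pentose interconversions, the pentose
#' phosphate pathway and pyruvate metabolism are carbon; the tricarboxylic
#' acid cycle is both. Unmatched subsystems get no macro-category.
#' Matching is case-insensitive. Each subsystem additionally gets one
#' display group (the nine-group axis used in the flux-shift summaries) or
#' "unmapped".
#'
#' @param subsystemNames subsystem labels to map.
#' @param displayGroups optional named character vector overriding or
#'   extending the built-in subsystem -> display-group lookup.
#' @return a [CategoryMap-class].
#' @examples
#' cm <- buildCategoryMap(c("urea cycle", "photosynthesis",
#'                          "tricarboxylic acid cycle"))
#' cm@macro[["tricarboxylic acid cycle"]]  # carbon and nitrogen
#' @export
buildCategoryMap <- function(subsystemNames,
                             displayGroups = DEFAULT_DISPLAY_GROUPS) {
  subsystemNames <- unique(as.character(subsystemNames))
  lowNames <- tolower(subsystemNames)
  macro <- lapply(lowNames, function(s) {
    cats <- character()
    if (s %in% BOTH_SUBSYSTEMS) cats <- c("carbon", "nitrogen")
    else {
      if (s %in% CARBON_SUBSYSTEMS) cats <- c(cats, "carbon")
      if (s %in% NITROGEN_SUBSYSTEMS) cats <- c(cats, "nitrogen")
    }
    cats
  })
  names(macro) <- subsystemNames
  lookup <- setNames(unname(displayGroups), tolower(names(displayGroups)))
  display <- lookup[lowNames]
  display[is.na(display)] <- "unmapped"
  names(display) <- subsystemNames
  new("CategoryMap", macro = macro, display = display)
}

# exact hypergeometric tails for a 2x2 enrichment table
hyperTails <- function(k, K, n, N) {
  list(over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       under = stats::phyper(k, K, N - K, n))
}

#' Hypergeometric term enrichment per cluster
#'
#' For every (cluster, term) pair, computes the exact hypergeometric tail
#' probabilities for over- and under-representation of the term among the
#' cluster's genes relative to the universe; the reported direction
#' ("enriched" / "purified") is the smaller tail and its probability the
#' p-value. No term-hierarchy propagation is performed: terms are opaque
#' strings. Benjamini-Hochberg adjustment runs across all pairs.
#'
#' @param clusters named list: cluster id -> character vector of gene ids.
#' @param geneTerms named list: gene id -> character vector of terms.
#' @param universe gene universe; defaults to the union of all cluster
#'   genes. Cluster genes outside the universe are an error.
#' @param alpha FDR significance threshold.
#' @return data.frame: `cluster`, `term`, `direction`, `p_value`,
#'   `q_value`, `k` (cluster genes with term), `n` (cluster size),
#'   `K` (universe genes with term), `N` (universe size), `significant`.
#' @export
enrichClusters <- function(clusters, geneTerms, universe = NULL,
                           alpha = 0.05) {
  stopifnot(length(clusters) > 0, !is.null(names(clusters)))
  if (is.null(universe)) universe <- unique(unlist(clusters))
  outside <- setdiff(unique(unlist(clusters)), universe)
  if (length(outside))
    stop("cluster gene(s) outside the universe: ",
         paste(head(outside, 10), collapse = ", "))
  N <- length(universe)
  termGenes <- list()
  for (g in intersect(names(geneTerms), universe))
    for (tm in geneTerms[[g]])
      termGenes[[tm]] <- c(termGenes[[tm]], g)
  rows <- list()
  for (cl in names(clusters)) {
    genes <- unique(clusters[[cl]])
    n <- length(genes)
    for (tm in names(termGenes)) {
      K <- length(termGenes[[tm]])
      k <- length(intersect(genes, termGenes[[tm]]))
      tails <- hyperTails(k, K, n, N)
      over <- tails$over <= tails$under
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, term = tm,
        direction = if (over) "enriched" else "purified",
        p_value = min(tails$over, tails$under),
        k = k, n = n, K = K, N = N, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out$significant <- out$q_value < alpha
  out[, c("cluster", "term", "direction", "p_value", "q_value",
          "k", "n", "K", "N", "significant")]
}

#' Flag clusters as carbon and/or nitrogen metabolism
#'
#' A cluster is flagged "carbon" (resp. "nitrogen") if any of its
#' significant enrichment records carries a term mapping to that
#' macro-category; a term like the tricarboxylic acid cycle contributes
#' both flags.
#'
#' @param records output of [enrichClusters()].
#' @param cmap a [CategoryMap-class] whose macro map covers the terms.
#' @param alpha significance threshold applied to the q-values.
#' @return named list: cluster id -> character vector drawn from
#'   `c("carbon", "nitrogen")` (possibly empty).
#' @export
flagCNClusters <- function(records, cmap, alpha = 0.05) {
  out <- lapply(unique(records$cluster), function(cl) {
    rec <- records[records$cluster == cl & records$q_value < alpha, ,
                   drop = FALSE]
    as.character(sort(unique(unlist(cmap@macro[rec$term]))))
  })
  names(out) <- unique(records$cluster)
  out
}

#' Substrate or product metabolite set of each cluster
#'
#' Joins cluster genes to reactions through the GPRs and unions the
#' reactions' substrate (or product) metabolites; reversible reactions
#' contribute their metabolites to both sides, and currency metabolites
#' are dropped by default so shared cofactors do not connect every
#' cluster.
#'
#' @param clusters named list: cluster id -> gene ids.
#' @param model a [MetabolicModel-class].
#' @param side "products" or "substrates".
#' @param dropCurrency drop currency metabolites ([currencyMetabolites()]).
#' @return named list: cluster id -> character vector of metabolite ids.
#' @export
clusterMetaboliteSets <- function(clusters, model,
                                  side = c("products", "substrates"),
                                  dropCurrency = TRUE) {
  side <- match.arg(side)
  geneRxns <- mapGenesToReactions(model, unique(unlist(clusters)))
  out <- lapply(clusters, function(genes) {
    rxns <- unique(unlist(geneRxns[genes]))
    mets <- unlist(lapply(rxns, function(r)
      reactionSides(model, r, dropCurrency = dropCurrency)[[side]]))
    as.character(sort(unique(mets)))
  })
  names(out) <- names(clusters)
  out
}

#' Cluster-metabolite connectivity graph
#'
#' Scores every cluster pair by the overlap of their metabolite sets and
#' connects the pairs scoring strictly above the threshold. The default
#' denominator is the union of the two sets (Jaccard similarity): with the
#' alternative "sum" denominator (`|A ∩ B| / (|A| + |B|)`) scores cannot
#' exceed 0.5, so a 0.9 threshold would disconnect everything.
#'
#' @param sets named list: cluster id -> metabolite ids
#'   ([clusterMetaboliteSets()]).
#' @param threshold edge threshold; edges require `score > threshold`
#'   (strict).
#' @param denominator "union" (Jaccard, default) or "sum".
#' @param side optional label ("products"/"substrates") stored as a graph
#'   attribute.
#' @return an undirected [igraph::igraph] with one node per cluster,
#'   edge attribute `weight` = connectivity score; clusters with empty
#'   sets stay as isolated nodes.
#' @export
connectivityGraph <- function(sets, threshold = 0.9,
                              denominator = c("union", "sum"),
                              side = NA_character_) {
  denominator <- match.arg(denominator)
  stopifnot(threshold >= 0, threshold <= 1)
  ids <- names(sets)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  edges <- list()
  if (length(ids) >= 2L) {
    for (pair in utils::combn(seq_along(ids), 2, simplify = FALSE)) {
      a <- sets[[pair[1]]]; b <- sets[[pair[2]]]
      inter <- length(intersect(a, b))
      den <- if (denominator == "union") length(union(a, b)) else
        length(a) + length(b)
      score <- if (den == 0L) 0 else inter / den
      if (score > threshold)
        edges[[length(edges) + 1L]] <- data.frame(
          from = ids[pair[1]], to = ids[pair[2]], weight = score,
          stringsAsFactors = FALSE)
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric())
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "denominator", denominator)
  igraph::set_graph_attr(g, "side", side)
}

#' Components and betweenness of a connectivity graph
#'
#' @param g graph from [connectivityGraph()].
#' @return list: `componentSizes` (decreasing), `membership` (named),
#'   `betweenness` (normalised fraction of all-pairs shortest paths
#'   through each node, on the unweighted topology).
#' @export
graphTopology <- function(g) {
  comp <- igraph::components(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  list(componentSizes = sort(unname(comp$csize), decreasing = TRUE),
       membership = comp$membership,
       betweenness = btw)
}
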