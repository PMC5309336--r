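#' Genes mentioned in a GPR expression
#'
#' Tokenises a boolean gene-protein-reaction string ("gA and (gB or gC)")
#' and returns the gene ids it mentions. Association is by mention: a gene
#' "participates" in a reaction if it appears anywhere in the GPR,
#' irrespective of the and/or structure, which is how gene-to-reaction
#' counts are tallied throughout the package.
#'
#' @param gpr character(1) GPR string; `""` or `NA` mean no association.
#' @return character vector of gene ids (possibly empty).
#' @examples
#' gprGenes("gA and (gB or gC)")
#' @export
gprGenes <- function(gpr) {
  if (is.null(gpr) || length(gpr) == 0L || is.na(gpr) || !nzchar(trimws(gpr)))
    return(character())
  toks <- strsplit(gsub("[()]", " ", gpr), "[[:space:]]+")[[1]]
  unique(toks[nzchar(toks) & !tolower(toks) %in% c("and", "or")])
}

# Recursive-descent parse of a GPR into an AST: list(op = "and"/"or",
# args = list(...)) or list(gene = "id"). Used by the SBML writer.
parseGPR <- function(gpr) {
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NULL
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parseFactor <- function() {
    t <- peek()
    if (is.null(t)) stop("malformed GPR: unexpected end in '", gpr, "'")
    if (t == "(") {
      advance()
      e <- parseOr()
      if (!identical(peek(), ")")) stop("malformed GPR: missing ')' in '", gpr, "'")
      advance()
      e
    } else if (t == ")") {
      stop("malformed GPR: unexpected ')' in '", gpr, "'")
    } else list(gene = advance())
  }
  parseAnd <- function() {
    args <- list(parseFactor())
    while (identical(tolower(peek() %||% ""), "and")) {
      advance(); args <- c(args, list(parseFactor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (identical(tolower(peek() %||% ""), "or")) {
      advance(); args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  out <- parseOr()
  if (pos <= length(toks)) stop("malformed GPR: trailing tokens in '", gpr, "'")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default currency metabolite list
#'
#' Ubiquitous cofactors and small species excluded from connectivity
#' analyses so that shared cofactors do not link every cluster: water, ATP,
#' ADP, AMP, NAD(H), NADP(H), protons, oxygen, inorganic phosphate,
#' pyrophosphate and CO2. Matching is compartment-agnostic on the
#' metabolite base id (the id with its compartment suffix removed), so
#' `atp_c` and `atp_m` are both currency while `hco3_c` is not.
#'
#' @return character vector of currency base ids.
#' @export
currencyMetabolites <- function() {
  c("h2o", "atp", "adp", "amp", "nad", "nadh", "nadp", "nadph",
    "h", "o2", "pi", "ppi", "co2")
}

# base id = metabolite id with its compartment suffix stripped
baseMetaboliteIds <- function(model) {
  m <- model@metabolites
  mapply(function(id, comp) sub(paste0("_", comp, "$"), "", id),
         m$id, m$compartment, USE.NAMES = TRUE)
}

#' Which metabolites are currency metabolites?
#'
#' @param model a [MetabolicModel-class].
#' @param metIds metabolite ids to classify (default: all).
#' @param currency currency base-id list, see [currencyMetabolites()].
#' @return named logical vector.
#' @export
isCurrency <- function(model, metIds = metaboliteIds(model),
                       currency = currencyMetabolites()) {
  base <- baseMetaboliteIds(model)
  out <- base[metIds] %in% currency
  names(out) <- metIds
  out
}

# Assemble a MetabolicModel from a metabolite table and a list of reaction
# records (id, stoichiometry = named numeric, lower_bound, upper_bound,
# gpr, subsystem, optional reversible).
buildModel <- function(metabolites, reactions, objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  rid <- vapply(reactions, `[[`, character(1), "id")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoichiometry
    if (length(st)) {
      idx <- match(names(st), metabolites$id)
      if (anyNA(idx))
        stop("reaction '", rid[j], "' references unknown metabolite(s): ",
             paste(names(st)[is.na(idx)], collapse = ", "))
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(st))); xx <- c(xx, unname(st))
    }
  }
  S <- sparseMatrix(i = ii, j = jj, x = xx,
                    dims = c(nrow(metabolites), length(reactions)),
                    dimnames = list(metabolites$id, rid))
  num <- function(f, d) vapply(reactions, function(r) as.numeric(r[[f]] %||% d),
                               numeric(1))
  chr <- function(f, d) vapply(reactions, function(r) as.character(r[[f]] %||% d),
                               character(1))
  lb <- num("lower_bound", 0); ub <- num("upper_bound", 1000)
  rev <- vapply(reactions, function(r)
    isTRUE(r$reversible %||% (as.numeric(r$lower_bound %||% 0) < 0 &&
                              as.numeric(r$upper_bound %||% 1000) > 0)),
    logical(1))
  rdf <- data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                    reversible = rev, gpr = chr("gpr", ""),
                    subsystem = chr("subsystem", ""),
                    stringsAsFactors = FALSE)
  new("MetabolicModel", metabolites = metabolites, reactions = rdf,
      stoichiometry = S, objective = objective)
}

#' Exchange reactions of a model
#'
#' An exchange reaction moves a single boundary-compartment metabolite in or
#' out of the system: its stoichiometric column has exactly one nonzero and
#' that metabolite lives in the boundary compartment (default `"e"`).
#' Single-metabolite reactions on internal metabolites are demand/sink
#' reactions, not exchanges.
#'
#' @param model a [MetabolicModel-class].
#' @param boundary compartment id regarded as extracellular.
#' @return character vector of reaction ids.
#' @export
exchangeReactions <- function(model, boundary = "e") {
  S <- model@stoichiometry
  nnz <- Matrix::colSums(S != 0)
  single <- which(nnz == 1L)
  comp <- setNames(model@metabolites$compartment, model@metabolites$id)
  keep <- vapply(single, function(j) {
    met <- rownames(S)[which(S[, j] != 0)]
    comp[[met]] == boundary
  }, logical(1))
  colnames(S)[single[keep]]
}

#' Construct a constraint set
#'
#' A constraint set is a table of per-reaction flux bounds, typically the
#' nutrient-uptake table of a growth condition. Uptake is negative flux; a
#' forced uptake of `u` mM is the equality bound `[-u, -u]`.
#'
#' @param reaction_id character vector of reaction ids.
#' @param lb,ub numeric lower/upper bounds (same length).
#' @return data.frame of class-tagged constraints with columns
#'   `reaction_id`, `lb`, `ub`.
#' @examples
#' constraintSet(c("EX_hco3_e", "EX_no3_e"), c(-1.57, -0.535), c(-1.57, -0.535))
#' @export
constraintSet <- function(reaction_id, lb, ub) {
  stopifnot(length(reaction_id) == length(lb), length(lb) == length(ub))
  if (any(lb > ub))
    stop("constraint with lower bound above upper bound: ",
         paste(reaction_id[lb > ub], collapse = ", "))
  data.frame(reaction_id = as.character(reaction_id), lb = as.numeric(lb),
             ub = as.numeric(ub), stringsAsFactors = FALSE)
}

#' Read / write a constraint table (TSV)
#'
#' Tab-separated with columns `reaction_id`, `lb`, `ub`; `#` lines are
#' comments.
#'
#' @param path file path.
#' @return for the reader, a validated constraint set data.frame.
#' @export
readConstraintTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("reaction_id", "lb", "ub")
  if (!all(need %in% names(df)))
    stop("constraint table needs columns: ", paste(need, collapse = ", "))
  constraintSet(df$reaction_id, df$lb, df$ub)
}

#' @rdname readConstraintTable
#' @param cs a constraint set ([constraintSet()]).
#' @export
writeConstraintTable <- function(cs, path) {
  utils::write.table(cs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply flux-bound constraints to a model
#'
#' Returns a copy of the model with the stated bounds applied. With
#' `blockOthers = TRUE`, every exchange reaction *not* named in the
#' constraint set is closed to `[0, 0]`, reflecting the convention that a
#' constraint table lists all permitted uptakes/secretions and everything
#' else is blocked.
#'
#' @param model a [MetabolicModel-class].
#' @param cs constraint set ([constraintSet()] / [readConstraintTable()]).
#' @param blockOthers close unlisted exchange reactions.
#' @param boundary boundary compartment for exchange detection.
#' @return the constrained [MetabolicModel-class]; applying the same set
#'   twice is a no-op.
#' @export
applyConstraints <- function(model, cs, blockOthers = FALSE, boundary = "e") {
  stopifnot(is(model, "MetabolicModel"))
  if (nrow(cs) > 0) {
    unknown <- setdiff(cs$reaction_id, reactionIds(model))
    if (length(unknown))
      stop("constraint set names unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    if (any(cs$lb > cs$ub))
      stop("constraint with lower bound above upper bound")
    idx <- match(cs$reaction_id, model@reactions$id)
    model@reactions$lower_bound[idx] <- cs$lb
    model@reactions$upper_bound[idx] <- cs$ub
  }
  if (blockOthers) {
    ex <- setdiff(exchangeReactions(model, boundary), cs$reaction_id)
    idx <- match(ex, model@reactions$id)
    model@reactions$lower_bound[idx] <- 0
    model@reactions$upper_bound[idx] <- 0
  }
  validObject(model)
  model
}

#' Substrate and product sets of a reaction
#'
#' Metabolites with negative stoichiometric coefficients are substrates,
#' positive ones products. For a reversible reaction each set is the union
#' of both sides, since either side can be consumed or produced. With
#' `dropCurrency`, currency metabolites (matched compartment-agnostically on
#' the base id) are removed from both sets.
#'
#' @param model a [MetabolicModel-class].
#' @param rxnId reaction id.
#' @param dropCurrency drop currency metabolites.
#' @param currency currency base-id list.
#' @return list with character vectors `substrates` and `products`.
#' @export
reactionSides <- function(model, rxnId, dropCurrency = FALSE,
                          currency = currencyMetabolites()) {
  j <- match(rxnId, reactionIds(model))
  if (is.na(j)) stop("unknown reaction: ", rxnId)
  col <- model@stoichiometry[, j]
  subs <- rownames(model@stoichiometry)[col < 0]
  prod <- rownames(model@stoichiometry)[col > 0]
  if (model@reactions$reversible[j]) {
    both <- union(subs, prod)
    subs <- both; prod <- both
  }
  if (dropCurrency) {
    base <- baseMetaboliteIds(model)
    subs <- subs[!base[subs] %in% currency]
    prod <- prod[!base[prod] %in% currency]
  }
  list(substrates = sort(subs), products = sort(prod))
}

#' Map genes to the reactions whose GPRs mention them
#'
#' @param model a [MetabolicModel-class].
#' @param genes character vector of gene ids; genes absent from every GPR
#'   map to `character(0)`.
#' @return named list gene id -> character vector of reaction ids.
#' @export
mapGenesToReactions <- function(model, genes) {
  rxnGenes <- lapply(model@reactions$gpr, gprGenes)
  out <- lapply(genes, function(g) {
    hit <- vapply(rxnGenes, function(gs) g %in% gs, logical(1))
    model@reactions$id[hit]
  })
  names(out) <- genes
  out
}
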