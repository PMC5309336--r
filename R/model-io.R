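#' Load a metabolic model from JSON or SBML
#'
#' Two on-disk formats are supported. The JSON dialect is a flat schema
#' (`objective`, `metabolites` with `id`/`name`/`compartment`, `reactions`
#' with a `stoichiometry` map, bounds, `gpr` string and `subsystem`) that
#' needs no XML tooling. The SBML form is Level 3 Version 1 with the `fbc`
#' extension: species, per-reaction flux-bound parameters, gene products
#' with a nested and/or `geneProductAssociation`, an active maximisation
#' objective, and the subsystem stored in the reaction notes. Both formats
#' round-trip exactly through [writeModel()].
#'
#' @param path file path.
#' @param format "json" or "sbml"; inferred from the file extension when
#'   omitted (`.json` vs `.xml`/`.sbml`).
#' @return a validated [MetabolicModel-class].
#' @examples
#' tmp <- tempfile(fileext = ".json")
#' writeModel(makeToyModel(), tmp)
#' loadModel(tmp)
#' @export
loadModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format, json = readModelJSON(path), sbml = readModelSBML(path))
}

#' @rdname loadModel
#' @param model a [MetabolicModel-class] to serialise.
#' @export
writeModel <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = writeModelJSON(model, path),
         sbml = writeModelSBML(model, path))
  invisible(path)
}

readModelJSON <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON model '", path,
                                           "': ", conditionMessage(e)))
  for (field in c("metabolites", "reactions")) {
    if (is.null(obj[[field]]))
      stop("malformed JSON model: missing '", field, "' element")
  }
  if (is.null(obj$objective) || !nzchar(obj$objective))
    stop("no objective defined in model '", path, "'")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed JSON model: metabolite without id")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    if (is.null(r$id)) stop("malformed JSON model: reaction without id")
    r$stoichiometry <- unlist(r$stoichiometry)
    r
  })
  model <- buildModel(mets, rxns, obj$objective)
  validObject(model)
  model
}

writeModelJSON <- function(model, path) {
  rxns <- lapply(seq_len(nReactions(model)), function(j) {
    col <- model@stoichiometry[, j]
    st <- col[col != 0]
    r <- model@reactions[j, ]
    list(id = r$id, stoichiometry = as.list(st),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         reversible = r$reversible, gpr = r$gpr, subsystem = r$subsystem)
  })
  mets <- lapply(seq_len(nMetabolites(model)), function(i) {
    m <- model@metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  out <- list(objective = model@objective, metabolites = mets,
              reactions = rxns)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

SBML_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

num17 <- function(x) sprintf("%.17g", x)

gprToFbc <- function(node, ast) {
  if (!is.null(ast$gene)) {
    xml2::xml_add_child(node, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", ast$gene))
  } else {
    sub <- xml2::xml_add_child(node, paste0("fbc:", ast$op))
    for (a in ast$args) gprToFbc(sub, a)
  }
}

fbcToGpr <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sub("^G_", "", xml2::xml_attr(node, "geneProduct"))
  } else if (nm %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), fbcToGpr, character(1), ns = ns)
    wrapped <- vapply(seq_along(parts), function(i) {
      child <- xml2::xml_children(node)[[i]]
      if (xml2::xml_name(child) %in% c("and", "or"))
        paste0("(", parts[i], ")") else parts[i]
    }, character(1))
    paste(wrapped, collapse = paste0(" ", nm, " "))
  } else stop("unexpected element in geneProductAssociation: ", nm)
}

writeModelSBML <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_CORE, "xmlns:fbc" = SBML_FBC,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")
  comps <- unique(model@metabolites$compartment)
  cl <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(cl, "compartment", id = cp, constant = "true")
  sl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nMetabolites(model))) {
    m <- model@metabolites[i, ]
    xml2::xml_add_child(sl, "species", id = paste0("M_", m$id), name = m$name,
                        compartment = m$compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (j in seq_len(nReactions(model))) {
    r <- model@reactions[j, ]
    xml2::xml_add_child(pl, "parameter", id = paste0("R_", r$id, "_lb"),
                        value = num17(r$lower_bound), constant = "true")
    xml2::xml_add_child(pl, "parameter", id = paste0("R_", r$id, "_ub"),
                        value = num17(r$upper_bound), constant = "true")
  }
  genes <- geneIds(model)
  gl <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
  for (g in genes)
    xml2::xml_add_child(gl, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                        "fbc:label" = g)
  ol <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  on <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model@objective),
                      "fbc:coefficient" = "1")
  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_len(nReactions(model))) {
    r <- model@reactions[j, ]
    rn <- xml2::xml_add_child(rl, "reaction", id = paste0("R_", r$id),
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("R_", r$id, "_lb"),
                              "fbc:upperFluxBound" = paste0("R_", r$id, "_ub"))
    if (nzchar(r$subsystem)) {
      nt <- xml2::xml_add_child(rn, "notes")
      bd <- xml2::xml_add_child(nt, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(bd, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    col <- model@stoichiometry[, j]
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs)) {
      ln <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in subs)
        xml2::xml_add_child(ln, "speciesReference",
                            species = paste0("M_", rownames(model@stoichiometry)[i]),
                            stoichiometry = num17(-col[i]), constant = "true")
    }
    if (length(prods)) {
      ln <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in prods)
        xml2::xml_add_child(ln, "speciesReference",
                            species = paste0("M_", rownames(model@stoichiometry)[i]),
                            stoichiometry = num17(col[i]), constant = "true")
    }
    if (nzchar(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      gprToFbc(ga, parseGPR(r$gpr))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

readModelSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(c = SBML_CORE, fbc = SBML_FBC)
  species <- xml2::xml_find_all(doc, ".//c:listOfSpecies/c:species", ns)
  if (!length(species)) stop("malformed SBML: no species in '", path, "'")
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(species, "id")),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  sub("^M_", "", xml2::xml_attr(species, "id")),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//c:listOfParameters/c:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))
  fobj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(fobj, "xml_missing"))
    stop("no objective defined in model '", path, "'")
  objective <- sub("^R_", "", xml2::xml_attr(fobj, "reaction"))
  rnodes <- xml2::xml_find_all(doc, ".//c:listOfReactions/c:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    id <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    lbRef <- xml2::xml_attr(rn, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(lbRef) || is.na(ubRef) || is.na(pval[lbRef]) || is.na(pval[ubRef]))
      stop("malformed SBML: reaction '", id, "' lacks resolvable flux bounds")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./c:listOfReactants/c:speciesReference", ns)) {
      met <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[met] <- (st[met] %|na|% 0) - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./c:listOfProducts/c:speciesReference", ns)) {
      met <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[met] <- (st[met] %|na|% 0) + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    ga <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(ga, "xml_missing")) "" else
      fbcToGpr(xml2::xml_child(ga), ns)
    note <- xml2::xml_find_first(rn, ".//c:notes//*[starts-with(text(), 'SUBSYSTEM:')]", ns)
    if (inherits(note, "xml_missing"))
      note <- xml2::xml_find_first(rn, ".//*[starts-with(text(), 'SUBSYSTEM:')]")
    subsystem <- if (inherits(note, "xml_missing")) "" else
      trimws(sub("^SUBSYSTEM:", "", xml2::xml_text(note)))
    list(id = id, stoichiometry = st, lower_bound = pval[[lbRef]],
         upper_bound = pval[[ubRef]],
         reversible = identical(xml2::xml_attr(rn, "reversible"), "true"),
         gpr = gpr, subsystem = subsystem)
  })
  model <- buildModel(mets, rxns, objective)
  validObject(model)
  model
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
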