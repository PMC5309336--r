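# 31-bit polynomial rolling hash of a string; used only for provenance headers
configHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenanceHeader <- function(config = list(), seeds = list()) {
  cfg <- paste(deparse(config), collapse = "")
  c(paste0("# cnflux ", as.character(utils::packageVersion("cnflux"))),
    paste0("# config_hash: ", configHash(cfg)),
    paste0("# seeds: ", paste(names(seeds), unlist(seeds), sep = "=",
                              collapse = " ")))
}

# write a data.frame as TSV with a provenance comment header
writeTsv <- function(df, path, config = list(), seeds = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(config, seeds), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a flux sample set as TSV plus JSON metadata sidecar
#'
#' The TSV holds one sampled flux vector per row with reaction ids as the
#' header; `<path>.meta.json` records seed, point and step counts, and the
#' condition label.
#'
#' @param fss a [FluxSampleSet-class].
#' @param path TSV path.
#' @return the path (writer) or a [FluxSampleSet-class] (reader).
#' @export
writeSampleSet <- function(fss, path) {
  utils::write.table(as.data.frame(samples(fss)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sampleMeta(fss), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSampleSet
#' @export
readSampleSet <- function(path) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  metaPath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metaPath))
    jsonlite::fromJSON(metaPath, simplifyVector = TRUE) else list()
  new("FluxSampleSet", samples = m, meta = as.list(meta))
}

#' Read cluster assignments / gene-term tables from TSV
#'
#' `readClusterTable` expects columns `cluster_id`, `gene_id` and returns
#' the named-list form the cluster analyses consume; `readGeneTermTable`
#' expects `gene_id`, `term`.
#'
#' @param path TSV path (`#` lines are comments).
#' @return named list (cluster -> genes, or gene -> terms).
#' @export
readClusterTable <- function(path) {
  df <- readTsv(path)
  if (!all(c("cluster_id", "gene_id") %in% names(df)))
    stop("cluster table needs columns cluster_id, gene_id")
  split(df$gene_id, df$cluster_id)
}

#' @rdname readClusterTable
#' @export
readGeneTermTable <- function(path) {
  df <- readTsv(path)
  if (!all(c("gene_id", "term") %in% names(df)))
    stop("gene-term table needs columns gene_id, term")
  split(df$term, df$gene_id)
}

#' Write a connectivity graph as a TSV edge list and as GraphML
#'
#' @param g graph from [connectivityGraph()].
#' @param path output path; `writeEdgeList` writes TSV (`cluster_a`,
#'   `cluster_b`, `score`, `side`), `writeGraphML` standard GraphML.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  ed <- igraph::as_data_frame(g, what = "edges")
  side <- igraph::graph_attr(g, "side")
  out <- data.frame(cluster_a = ed$from, cluster_b = ed$to,
                    score = ed$weight,
                    side = if (is.null(side)) NA_character_ else side,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
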