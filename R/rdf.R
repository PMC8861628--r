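#' Minimal in-memory RDF triple store
#'
#' The knowledge fixtures used throughout the package are plain RDF graphs.
#' They are small (hundreds of triples), so a data-frame-backed triple store
#' with Turtle serialization is sufficient and keeps every fixture
#' human-diffable.  Objects are either IRIs or plain literals; language tags
#' and datatypes are not needed for the extraction operations and are not
#' modelled.
#'
#' @param s,p,o character vectors of equal length: subject IRI, predicate IRI,
#'   object (IRI or literal).
#' @param o_literal logical vector; `TRUE` where the object is a literal.
#' @return An object of class `rdf_graph`: a data frame with columns
#'   `s`, `p`, `o`, `o_literal`.
#' @export
rdf_graph <- function(s = character(), p = character(), o = character(),
                      o_literal = logical(length(o))) {
  stopifnot(length(s) == length(p), length(p) == length(o),
            length(o) == length(o_literal))
  g <- data.frame(s = as.character(s), p = as.character(p),
                  o = as.character(o), o_literal = as.logical(o_literal),
                  stringsAsFactors = FALSE)
  class(g) <- c("rdf_graph", "data.frame")
  g
}

#' Append triples to a graph
#' @param graph an [rdf_graph()].
#' @inheritParams rdf_graph
#' @return the extended graph.
#' @export
rdf_add <- function(graph, s, p, o, o_literal = logical(length(o))) {
  n <- max(length(s), length(p), length(o))
  add <- rdf_graph(rep_len(s, n), rep_len(p, n), rep_len(o, n),
                   rep_len(o_literal, n))
  out <- rbind(graph, add)
  class(out) <- c("rdf_graph", "data.frame")
  out
}

#' Match triples by pattern
#'
#' `NULL` components act as wildcards, mirroring a basic graph pattern with a
#' single triple.
#'
#' @param graph an [rdf_graph()].
#' @param s,p,o optional subject / predicate / object values to match.
#' @return the matching rows of the graph.
#' @export
rdf_match <- function(graph, s = NULL, p = NULL, o = NULL) {
  keep <- rep(TRUE, nrow(graph))
  if (!is.null(s)) keep <- keep & graph$s %in% s
  if (!is.null(p)) keep <- keep & graph$p %in% p
  if (!is.null(o)) keep <- keep & graph$o %in% o
  out <- graph[keep, , drop = FALSE]
  class(out) <- c("rdf_graph", "data.frame")
  out
}

#' Object values for a (subject, predicate) pair
#' @inheritParams rdf_match
#' @return character vector of objects (possibly empty).
#' @export
rdf_objects <- function(graph, s = NULL, p = NULL) {
  rdf_match(graph, s = s, p = p)$o
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triples, %d subjects>\n",
              nrow(x), length(unique(x$s))))
  invisible(x)
}

ttl_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  gsub("\"", "\\\\\"", x)
}

ttl_unescape <- function(x) {
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

#' Serialize a graph to Turtle
#'
#' One triple per line, absolute IRIs, UTF-8.  This is the subset of Turtle
#' that [read_turtle()] parses back; round-tripping is exact.
#'
#' @param graph an [rdf_graph()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(graph, path) {
  obj <- ifelse(graph$o_literal,
                paste0("\"", ttl_escape(graph$o), "\""),
                paste0("<", graph$o, ">"))
  lines <- paste0("<", graph$s, "> <", graph$p, "> ", obj, " .")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Read a Turtle file written by [write_turtle()]
#' @param path file to read.
#' @return an [rdf_graph()].
#' @export
read_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^<([^>]*)> <([^>]*)> (<([^>]*)>|\"(.*)\") \\.$", lines))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("unparseable Turtle line(s): ", which(bad)[1])
  s <- vapply(m, `[`, "", 2L)
  p <- vapply(m, `[`, "", 3L)
  iri <- vapply(m, `[`, "", 5L)
  lit <- vapply(m, `[`, "", 6L)
  is_lit <- !nzchar(iri) & grepl("^\"", vapply(m, `[`, "", 4L))
  o <- ifelse(is_lit, ttl_unescape(lit), iri)
  rdf_graph(s, p, o, is_lit)
}

# Predicate and class IRIs shared by the fixture generator and the extraction
# operations.  The Wikidata-like drug relations are keyed by LABEL (role /
# interaction / condition); the IRIs below are defaults and can be remapped
# via options in wikidata_pairs().
kg_iri <- list(
  subclassof   = "http://www.w3.org/2000/01/rdf-schema#subClassOf",
  broader      = "http://www.w3.org/2004/02/skos/core#broader",
  preflabel    = "http://www.w3.org/2004/02/skos/core#prefLabel",
  subject      = "http://purl.org/dc/terms/subject",
  sameas       = "http://www.w3.org/2002/07/owl#sameAs",
  rdftype      = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
  cui          = "urn:kg:prop:umls-cui",
  rxnorm       = "urn:kg:prop:rxnorm-cui",
  wd_atc       = "urn:kg:prop:wdt-P267",
  wd_cui       = "urn:kg:prop:wdt-P2892",
  wd_rxnorm    = "urn:kg:prop:wdt-P3345",
  wd_role      = "urn:kg:prop:wdt-P2868",
  wd_interact  = "urn:kg:prop:wdt-P2175",
  wd_condition = "urn:kg:prop:wdt-P769",
  may_treat    = "urn:kg:prop:ndfrt-may_treat",
  may_prevent  = "urn:kg:prop:ndfrt-may_prevent",
  ci_with      = "urn:kg:prop:ndfrt-CI_with"
)

#' Preferred label of a node
#' @param graph an [rdf_graph()].
#' @param iri node IRI.
#' @return the `skos:prefLabel` literal, or the IRI fragment when unlabeled.
#' @export
node_label <- function(graph, iri) {
  lab <- rdf_objects(graph, s = iri, p = kg_iri$preflabel)
  if (length(lab)) lab[[1]] else sub("^.*[:/]", "", iri)
}
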