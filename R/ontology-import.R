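# Bio-ontology import (SBO, GO slices, KiSAO) into concept nodes with isA
# edges. Two plain-text encodings are accepted: OBO 1.2 flat files and an
# OWL-XML subset (named classes, rdfs:label, rdfs:subClassOf between named
# classes, textual definitions). Only isA relations are mapped; other
# relationship types and cross-ontology references are dropped with a
# count. No description-logic reasoning: every query in scope needs only
# the structural isA closure.

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list(); cur <- NULL; in_term <- FALSE
  dropped <- 0L
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id))
      terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$label <- trimws(sub("^name:", "", ln))
    else if (grepl("^def:", ln)) {
      d <- trimws(sub("^def:", "", ln))
      m <- regmatches(d, regexpr('"[^"]*"', d))
      cur$def <- if (length(m)) gsub('^"|"$', "", m) else d
    } else if (grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, p)
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    else if (grepl("^relationship:", ln)) dropped <- dropped + 1L
    else if (grepl("^xref:", ln)) dropped <- dropped + 1L
  }
  flush()
  list(terms = terms, dropped = dropped)
}

owl_local_name <- function(uri) sub(".*[#/]", "", uri)

parse_owl_xml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(owl = "http://www.w3.org/2002/07/owl#",
          rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#")
  classes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about]", ns)
  terms <- list(); dropped <- 0L
  for (cl in classes) {
    id <- owl_local_name(xml2::xml_attr(cl, "about"))
    lab <- xml2::xml_text(xml2::xml_find_first(cl, "./rdfs:label", ns))
    def <- xml2::xml_text(xml2::xml_find_first(
      cl, "./*[local-name()='IAO_0000115' or local-name()='comment']"))
    parents <- character()
    for (sc in xml2::xml_find_all(cl, "./rdfs:subClassOf", ns)) {
      r <- xml2::xml_attr(sc, "resource")
      if (!is.na(r)) parents <- c(parents, owl_local_name(r))
      else dropped <- dropped + 1L   # anonymous restriction, not isA
    }
    terms[[length(terms) + 1L]] <- list(
      id = id, label = if (is.na(lab)) NULL else lab,
      def = if (is.na(def) || !nzchar(def)) NULL else def,
      parents = parents)
  }
  list(terms = terms, dropped = dropped)
}

# id forms vary across encodings: SBO:0000009 vs SBO_0000009
concept_id_forms <- function(id) unique(c(id, gsub(":", "_", id), gsub("_", ":", id)))

ontology_registry <- function(g) {
  if (is.null(g$ontologies)) g$ontologies <- new.env(parent = emptyenv())
  g$ontologies
}

concept_index <- function(g) {
  if (is.null(g$concepts)) g$concepts <- new.env(parent = emptyenv())
  g$concepts
}

#' Import a bio-ontology into a property graph
#'
#' Reads an OBO 1.2 flat file or an OWL-XML subset and adds an ontology
#' root node plus one concept node per term, labelled `<tag>Ontology`
#' (e.g. `SBOOntology`) with `id`, `NAME` and `DEFINITION` attributes,
#' and `isA` edges child -> parent. A cyclic isA graph or a repeated tag
#' aborts the import. Relations other than isA are dropped and counted.
#'
#' @param g A `property_graph`.
#' @param path Path to an `.obo` or OWL-XML file (format sniffed from
#'   content).
#' @param tag Short ontology tag (`"SBO"`, `"GO"`, `"KISAO"`, ...), used
#'   for the node label and later suffix-match linking.
#' @return Named counts: `concepts`, `isa_edges`, `dropped_relations`.
#' @export
import_ontology <- function(g, path, tag) {
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  reg <- ontology_registry(g)
  if (exists(tag, envir = reg, inherits = FALSE))
    stop("ontology tag already imported: ", tag)
  head_txt <- readChar(path, 256L, useBytes = TRUE)
  parsed <- if (grepl("<\\?xml|<rdf:RDF|<owl", head_txt)) parse_owl_xml(path)
            else if (grepl("format-version:|\\[Term\\]", head_txt)) parse_obo(path)
            else stop("unknown ontology format: ", path)
  terms <- parsed$terms
  if (length(terms) == 0L) stop("no concepts found in ", path)
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate concept ids in ", path)

  # acyclicity of isA before anything is written
  parents <- stats::setNames(lapply(terms, `[[`, "parents"), ids)
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(id, trail) {
    if (!(id %in% ids)) return(invisible())
    if (state[[id]] == 1L)
      stop("cyclic isA relation involving: ",
           paste(c(trail, id), collapse = " -> "))
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (p in parents[[id]]) visit(p, c(trail, id))
    state[[id]] <<- 2L
  }
  for (id in ids) visit(id, character())

  lab <- paste0(tag, "Ontology")
  root <- pg_add_node(g, c("ONTOLOGY_ROOT", lab), list(TAG = tag))
  assign(tag, root, envir = reg)
  cidx <- concept_index(g)
  node_of <- list()
  for (t in terms) {
    attrs <- list(id = t$id)
    if (!is.null(t$label)) attrs$NAME <- t$label
    if (!is.null(t$def)) attrs$DEFINITION <- t$def
    nid <- pg_add_node(g, c(lab, "ONTOLOGY_CONCEPT"), attrs)
    node_of[[t$id]] <- nid
    for (form in concept_id_forms(t$id)) assign(form, nid, envir = cidx)
  }
  n_isa <- 0L
  for (t in terms) {
    known <- t$parents[t$parents %in% ids]
    for (p in known) {
      pg_add_edge(g, node_of[[t$id]], node_of[[p]], "isA")
      n_isa <- n_isa + 1L
    }
    if (length(known) == 0L)
      pg_add_edge(g, root, node_of[[t$id]], "hasConcept")
  }
  c(concepts = length(terms), isa_edges = n_isa,
    dropped_relations = parsed$dropped +
      sum(vapply(terms, function(t)
        sum(!(t$parents %in% ids)), integer(1))))
}

#' Resolve a concept id to its node
#' @param g A `property_graph`.
#' @param concept_id Concept id (colon or underscore form).
#' @return Node id, or an error for an unknown concept.
#' @export
concept_node <- function(g, concept_id) {
  cidx <- concept_index(g)
  for (form in concept_id_forms(concept_id))
    if (exists(form, envir = cidx, inherits = FALSE))
      return(get(form, envir = cidx))
  stop("unknown ontology concept: ", concept_id)
}

#' Transitive isA closure downward (descendants, self included)
#'
#' @param g A `property_graph`.
#' @param concept_id Concept id; colon and underscore forms both resolve.
#' @return Character vector of concept ids: the concept and all its
#'   transitive descendants (hop 0 upward closure of `isA`).
#' @export
descendants <- function(g, concept_id) {
  start <- concept_node(g, concept_id)
  nodes <- pg_traverse(g, start, "isA", "in", 0L, Inf)
  sort(vapply(nodes, function(n) pg_attr(g, n, "id"), character(1)))
}
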