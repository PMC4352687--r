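# Shared MIRIAM/RDF annotation handling for the SBML and CellML importers.
#
# Scheme in the store (fixed direction conventions so that every printed
# query pattern holds):
#   element  -[hasAnnotation]-> ANNOTATION
#   ANNOTATION -[BELONGS_TO]-> element
#   ANNOTATION -[<qualifier>]-> RESOURCE     (is, isVersionOf, hasPart, ...)
#   RESOURCE -[BELONGS_TO]-> ANNOTATION

RDF_NS <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  bqbiol = "http://biomodels.net/biology-qualifiers/",
  bqmodel = "http://biomodels.net/model-qualifiers/"
)

KNOWN_QUALIFIERS <- c(
  "is", "isVersionOf", "hasPart", "isPartOf", "isDescribedBy",
  "hasVersion", "isHomologTo", "isEncodedBy", "encodes", "occursIn",
  "hasProperty", "isPropertyOf", "hasTaxon", "isDerivedFrom", "isInstanceOf"
)

# Pull (qualifier, resource URIs) pairs out of an element's RDF block.
extract_rdf_annotations <- function(xml_node) {
  descs <- xml2::xml_find_all(xml_node, ".//rdf:Description", RDF_NS)
  out <- list()
  for (d in descs) {
    for (q in xml2::xml_children(d)) {
      qual <- xml2::xml_name(q)   # local name, namespace stripped
      uris <- xml2::xml_attr(
        xml2::xml_find_all(q, ".//rdf:li", RDF_NS), "resource")
      uris <- uris[!is.na(uris)]
      if (length(uris))
        out[[length(out) + 1L]] <- list(qualifier = qual, uris = uris)
    }
  }
  out
}

# Deduplicated RESOURCE node per canonical URI key; index lives with the
# store so two importers hitting the same concept share one node.
resource_index <- function(g) {
  if (is.null(g$resources))
    g$resources <- new.env(parent = emptyenv())
  g$resources
}

#' Get or create the deduplicated RESOURCE node for a URI
#'
#' Each external concept URI is stored only once; the node carries the
#' verbatim `URI`, the canonical `KEY`, `COLLECTION` and `ACCESSION`, and a
#' `RESOURCETEXT` seed derived from the accession (later extended by
#' ontology linking or a resource-description table). PubMed resources are
#' additionally labelled `PUBLICATION` so shared reference publications can
#' gate cross-format linking.
#'
#' @param g A `property_graph`.
#' @param uri Resource URI as written in the document.
#' @return Node id of the RESOURCE node.
#' @export
pg_resource_node <- function(g, uri) {
  info <- normalize_uri(uri)
  idx <- resource_index(g)
  if (exists(info$key, envir = idx, inherits = FALSE))
    return(get(info$key, envir = idx))
  seed <- gsub("[^A-Za-z0-9]+", " ",
               if (info$parsed) info$accession else uri)
  labels <- "RESOURCE"
  if (identical(info$collection, "pubmed")) labels <- c(labels, "PUBLICATION")
  id <- pg_add_node(g, labels, list(
    URI = uri, KEY = info$key,
    COLLECTION = info$collection, ACCESSION = info$accession,
    RESOURCETEXT = trimws(seed)))
  assign(info$key, id, envir = idx)
  id
}

# Map one element's annotation list onto the store. Returns the ANNOTATION
# node id or NA if there was nothing to map. Unknown qualifiers map to a
# generic edge with a warning collected by the caller.
map_annotations <- function(g, element_id, ann_list, warnings = NULL) {
  if (length(ann_list) == 0L) return(list(ann = NA_integer_, warnings = warnings))
  ann <- pg_add_node(g, "ANNOTATION", list())
  pg_add_edge(g, element_id, ann, "hasAnnotation")
  pg_add_edge(g, ann, element_id, "BELONGS_TO")
  for (a in ann_list) {
    qual <- a$qualifier
    if (!(qual %in% KNOWN_QUALIFIERS)) {
      warnings <- c(warnings,
                    sprintf("unknown qualifier '%s'; kept as generic edge", qual))
    }
    for (uri in a$uris) {
      res <- pg_resource_node(g, uri)
      pg_add_edge(g, ann, res, qual)
      # one BELONGS_TO back-edge per (resource, annotation) pair
      existing <- vapply(pg_incident_edges(g, res, "BELONGS_TO", "out"),
                         function(e) e$target, integer(1))
      if (!(ann %in% existing)) pg_add_edge(g, res, ann, "BELONGS_TO")
    }
  }
  list(ann = ann, warnings = warnings)
}

#' Load a resource-description table into the store
#'
#' A tab-separated table (URI, description text) that supplies descriptive
#' text for non-ontology resources such as UniProt or InterPro records,
#' standing in for live web look-ups. Descriptions are appended to the
#' matching RESOURCE nodes' `RESOURCETEXT` and hence enter the full-text
#' index.
#'
#' @param g A `property_graph`.
#' @param path Path to a two-column TSV (no header): URI, description.
#' @return Number of resource nodes updated.
#' @export
load_resource_descriptions <- function(g, path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected two tab-separated columns: URI, text")
  idx <- resource_index(g)
  n <- 0L
  for (i in seq_len(nrow(tab))) {
    key <- normalize_uri(tab[i, 1])$key
    if (exists(key, envir = idx, inherits = FALSE)) {
      id <- get(key, envir = idx)
      cur <- pg_attr(g, id, "RESOURCETEXT")
      pg_set_attrs(g, id, list(
        RESOURCETEXT = trimws(paste(cur, tab[i, 2]))))
      n <- n + 1L
    }
  }
  n
}
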