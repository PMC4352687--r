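# CellML 1.0/1.1 to graph mapping.
#
# Document root -> hasModel -> CELLML_MODEL; components attach via
# hasComponent, their variables via hasVariable, all with BELONGS_TO
# back-edges. Each map_variables entry of a connection becomes one
# MAPPED_TO edge between the two variable nodes (stored once, matched
# undirected, since CellML connections are symmetric). RDF metadata uses
# the same annotation/RESOURCE scheme as the SBML importer, so a shared
# reference publication collapses onto one PubMed node.

CELLML_NS_RE <- "cellml\\.org/cellml/1\\.[01]"

#' Import a CellML document into a property graph
#'
#' Accepts CellML 1.0 and 1.1; later versions are rejected. Creates a
#' `DOCUMENT` node, a `CELLML_MODEL` node (`NAME`), one `CELLMLCOMPONENT`
#' node per component and one `CELLMLVARIABLE` node per variable. RDF
#' annotations are attached to the model or, when a `cmeta:id` matches,
#' to the corresponding element. Connections referencing unknown
#' components or variables are recorded in `unresolved_connections`
#' rather than failing the import.
#'
#' @param g A `property_graph`.
#' @param path Path to a CellML XML file.
#' @param filename Stored `FILENAME`; defaults to `basename(path)`.
#' @return Import report with `document_node`, `model_node`, `counts`,
#'   `unresolved_connections` (list of component/variable pairs) and
#'   `warnings`.
#' @export
import_cellml <- function(g, path, filename = basename(path)) {
  doc <- xml2::read_xml(path)
  ns <- unlist(xml2::xml_ns(doc))
  if (xml2::xml_name(doc) != "model" || !any(grepl("cellml\\.org/cellml/", ns)))
    stop("not a CellML document: ", filename)
  if (!any(grepl(CELLML_NS_RE, ns)))
    stop("unsupported CellML version (only 1.0/1.1 accepted): ", filename)

  warnings <- character()
  unresolved <- list()
  n0 <- pg_node_count(g)
  document <- pg_add_node(g, "DOCUMENT", list(FILENAME = filename))
  mname <- xattr(doc, "name")
  mnode <- pg_add_node(g, "CELLML_MODEL",
                       if (is.null(mname)) list() else list(NAME = mname))
  pg_add_edge(g, document, mnode, "hasModel")
  pg_add_edge(g, mnode, document, "BELONGS_TO")

  # cmeta:id -> node, for attaching RDF descriptions to elements
  meta_ids <- list()
  register_meta <- function(node, id) {
    at <- xml2::xml_attrs(node)
    # CellML elements carry no plain "id", so a local-name match is the
    # cmeta:id regardless of how the prefix was serialized
    key <- at[grepl("(^|:)id$", names(at))]
    if (length(key)) meta_ids[[key[[1]]]] <<- id
  }
  register_meta(doc, mnode)

  comp_nodes <- list(); var_nodes <- list()
  for (comp in xchildren(doc, "component")) {
    cname <- xattr(comp, "name")
    math <- verbatim_math(comp)
    cid <- pg_add_node(g, "CELLMLCOMPONENT",
                       c(list(NAME = cname),
                         if (is.null(math)) list() else list(MATH = math)))
    pg_add_edge(g, mnode, cid, "hasComponent")
    pg_add_edge(g, cid, mnode, "BELONGS_TO")
    register_meta(comp, cid)
    comp_nodes[[cname]] <- cid
    for (v in xchildren(comp, "variable")) {
      vname <- xattr(v, "name")
      vid <- pg_add_node(g, "CELLMLVARIABLE", list(NAME = vname))
      pg_add_edge(g, cid, vid, "hasVariable")
      pg_add_edge(g, vid, cid, "BELONGS_TO")
      register_meta(v, vid)
      var_nodes[[paste(cname, vname, sep = "\r")]] <- vid
    }
  }

  for (conn in xchildren(doc, "connection")) {
    mc <- xchildren(conn, "map_components")
    if (!length(mc)) next
    c1 <- xml2::xml_attr(mc[[1]], "component_1")
    c2 <- xml2::xml_attr(mc[[1]], "component_2")
    for (mv in xchildren(conn, "map_variables")) {
      v1 <- xml2::xml_attr(mv, "variable_1")
      v2 <- xml2::xml_attr(mv, "variable_2")
      n1 <- var_nodes[[paste(c1, v1, sep = "\r")]]
      n2 <- var_nodes[[paste(c2, v2, sep = "\r")]]
      if (is.null(n1)) { unresolved <- c(unresolved, list(c(c1, v1))); next }
      if (is.null(n2)) { unresolved <- c(unresolved, list(c(c2, v2))); next }
      pg_add_edge(g, n1, n2, "MAPPED_TO")
    }
  }

  # RDF metadata: descriptions about "#<cmeta:id>" attach to that element,
  # everything else to the model node
  for (rdf in xml2::xml_find_all(doc, "./rdf:RDF", RDF_NS)) {
    for (d in xml2::xml_find_all(rdf, "./rdf:Description", RDF_NS)) {
      about <- xml2::xml_attr(d, "about")
      target <- mnode
      if (!is.na(about) && nzchar(about)) {
        key <- sub("^#", "", about)
        if (!is.null(meta_ids[[key]])) target <- meta_ids[[key]]
      }
      anns <- list()
      for (q in xml2::xml_children(d)) {
        uris <- xml2::xml_attr(
          xml2::xml_find_all(q, ".//rdf:li", RDF_NS), "resource")
        uris <- uris[!is.na(uris)]
        if (length(uris))
          anns[[length(anns) + 1L]] <-
            list(qualifier = xml2::xml_name(q), uris = uris)
      }
      res <- map_annotations(g, target, anns, warnings)
      warnings <- res$warnings
    }
  }

  structure(list(document_node = document, model_node = mnode,
                 counts = label_delta(g, n0),
                 unresolved_connections = unresolved,
                 warnings = warnings),
            class = "cellml_import_report")
}

#' @export
print.cellml_import_report <- function(x, ...) {
  cat("CellML import: document node", x$document_node, "\n")
  print(x$counts)
  if (length(x$unresolved_connections))
    cat(length(x$unresolved_connections), "unresolved connection(s)\n")
  invisible(x)
}
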