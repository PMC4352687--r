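# SBML (Level 2 / Level 3 core) to graph mapping.
#
# Document root -> hasModel -> model node; model connects to species,
# reaction, compartment, parameter and function nodes; every created node
# points back to its parent via BELONGS_TO so the document is reachable
# upwards. Species are placed in compartments via isContainedIn and take
# part in reactions via IS_REACTANT / IS_PRODUCT / IS_MODIFIER edges
# (species -> reaction). Unit declarations are skipped and reported.

# local-name() child selection keeps the importer independent of the
# default-namespace prefix games across SBML levels/versions
xchildren <- function(node, ...) {
  steps <- vapply(c(...), function(n) sprintf("*[local-name()='%s']", n),
                  character(1))
  xml2::xml_find_all(node, paste0("./", paste(steps, collapse = "/")))
}

xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

# NAME falls back to ID so name-keyed queries work on sparsely named models
name_or_id <- function(node) {
  nm <- xattr(node, "name")
  if (is.null(nm)) xattr(node, "id") else nm
}

element_attrs <- function(node) {
  a <- list()
  id <- xattr(node, "id"); nm <- name_or_id(node)
  if (!is.null(id)) a$ID <- id
  if (!is.null(nm)) a$NAME <- nm
  a
}

verbatim_math <- function(node) {
  m <- xchildren(node, "math")
  if (length(m) == 0) NULL else as.character(m[[1]])
}

#' Import an SBML document into a property graph
#'
#' Maps an SBML Level 2 or Level 3 core model onto the store: a `DOCUMENT`
#' root (with `FILENAME`), an `SBML_MODEL` node and one node per species,
#' reaction, compartment, global parameter, function definition, rule and
#' event. Reaction roles become directed `IS_REACTANT` / `IS_PRODUCT` /
#' `IS_MODIFIER` edges from the species to the reaction; a species with a
#' compartment gains one `isContainedIn` edge. MIRIAM RDF annotations are
#' mapped to `ANNOTATION` and deduplicated `RESOURCE` nodes; PubMed
#' resources double as shared publication nodes. Unit definitions are
#' skipped and reported; SBML packages (comp, fbc) are ignored with a
#' warning.
#'
#' @param path Path to an SBML XML file.
#' @param g A `property_graph` to import into.
#' @param filename Stored `FILENAME` attribute; defaults to the basename
#'   of `path`.
#' @return An import report: `document_node`, `model_node`, `counts`
#'   (named integer vector of created nodes per label), `skipped`,
#'   `warnings`.
#' @export
import_sbml <- function(g, path, filename = basename(path)) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  ns_uri <- xml2::xml_ns(doc)
  if (root != "sbml" || !any(grepl("sbml.org/sbml/level[23]", unlist(ns_uri))))
    stop("not an SBML Level 2/3 document: ", filename)
  model <- xchildren(doc, "model")
  if (length(model) == 0) stop("SBML import error: no model element in ", filename)
  model <- model[[1]]

  warnings <- character(); skipped <- character()
  if (length(xchildren(doc, "listOfUnitDefinitions")) ||
      length(xchildren(model, "listOfUnitDefinitions")))
    skipped <- c(skipped, "unitDefinitions")
  pkg_ns <- grep("comp|fbc", names(unlist(ns_uri)), value = TRUE)
  if (any(grepl("/(comp|fbc)/version", unlist(ns_uri))))
    warnings <- c(warnings, "SBML package namespaces (comp/fbc) ignored")

  n0 <- pg_node_count(g)
  document <- pg_add_node(g, "DOCUMENT", list(FILENAME = filename))
  m_attrs <- element_attrs(model)
  mnode <- pg_add_node(g, "SBML_MODEL", m_attrs)
  pg_add_edge(g, document, mnode, "hasModel")
  pg_add_edge(g, mnode, document, "BELONGS_TO")

  add_element <- function(node, label, forward_edge, parent = mnode,
                          extra = list()) {
    id <- pg_add_node(g, label, c(element_attrs(node), extra))
    pg_add_edge(g, parent, id, forward_edge)
    pg_add_edge(g, id, parent, "BELONGS_TO")
    res <- map_annotations(g, id, extract_rdf_annotations_shallow(node),
                           warnings)
    warnings <<- res$warnings
    id
  }

  # model-level annotations (carries the reference publication)
  res <- map_annotations(g, mnode, extract_rdf_annotations_shallow(model),
                         warnings)
  warnings <- res$warnings

  comp_ids <- list()
  for (c_ in xchildren(model, "listOfCompartments", "compartment"))
    comp_ids[[xattr(c_, "id")]] <-
      add_element(c_, "SBML_COMPARTMENT", "hasCompartment")

  sp_ids <- list()
  for (s in xchildren(model, "listOfSpecies", "species")) {
    sid <- add_element(s, "SBML_SPECIES", "hasSpecies")
    sp_ids[[xattr(s, "id")]] <- sid
    comp <- xattr(s, "compartment")
    if (!is.null(comp) && !is.null(comp_ids[[comp]]))
      pg_add_edge(g, sid, comp_ids[[comp]], "isContainedIn")
  }

  for (p in xchildren(model, "listOfParameters", "parameter"))
    add_element(p, "SBML_PARAMETER", "hasParameter")
  for (f in xchildren(model, "listOfFunctionDefinitions", "functionDefinition"))
    add_element(f, "SBML_FUNCTION", "hasFunction")
  for (r in xchildren(model, "listOfRules")) {
    for (rule in xml2::xml_children(r))
      add_element(rule, "SBML_RULE", "hasRule")
  }
  for (e in xchildren(model, "listOfEvents", "event"))
    add_element(e, "SBML_EVENT", "hasEvent")

  role_edges <- list(listOfReactants = "IS_REACTANT",
                     listOfProducts = "IS_PRODUCT",
                     listOfModifiers = "IS_MODIFIER")
  for (rx in xchildren(model, "listOfReactions", "reaction")) {
    math <- NULL
    kl <- xchildren(rx, "kineticLaw")
    if (length(kl)) math <- verbatim_math(kl[[1]])
    rid <- add_element(rx, "SBML_REACTION", "hasReaction",
                       extra = if (is.null(math)) list() else list(MATH = math))
    for (lname in names(role_edges)) {
      refs <- xchildren(rx, lname)
      if (!length(refs)) next
      stoich <- list()  # collapse repeated roles to one edge, summed
      for (sr in xml2::xml_children(refs[[1]])) {
        sp <- xattr(sr, "species")
        if (is.null(sp)) next
        st <- xattr(sr, "stoichiometry")
        st <- if (is.null(st)) 1 else as.numeric(st)
        stoich[[sp]] <- (if (is.null(stoich[[sp]])) 0 else stoich[[sp]]) + st
      }
      for (sp in names(stoich)) {
        if (is.null(sp_ids[[sp]])) {
          warnings <- c(warnings, sprintf(
            "reaction %s references unknown species %s",
            xattr(rx, "id"), sp))
          next
        }
        pg_add_edge(g, sp_ids[[sp]], rid, role_edges[[lname]],
                    list(stoichiometry = stoich[[sp]]))
      }
    }
    # local (per-reaction) parameters attach to the reaction
    if (length(kl)) {
      for (lp in c(xchildren(kl[[1]], "listOfParameters", "parameter"),
                   xchildren(kl[[1]], "listOfLocalParameters", "localParameter")))
        add_element(lp, "SBML_PARAMETER", "hasParameter", parent = rid)
    }
  }

  counts <- label_delta(g, n0)
  structure(list(document_node = document, model_node = mnode,
                 counts = counts, skipped = skipped, warnings = warnings),
            class = "sbml_import_report")
}

# annotations directly under this element (not those of nested children)
extract_rdf_annotations_shallow <- function(node) {
  anns <- xchildren(node, "annotation")
  out <- list()
  for (a in anns) out <- c(out, extract_rdf_annotations(a))
  out
}

label_delta <- function(g, n0) {
  labs <- character()
  for (id in seq.int(n0 + 1L, length.out = pg_node_count(g) - n0))
    labs <- c(labs, pg_labels(g, id)[1])
  tab <- table(labs)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.sbml_import_report <- function(x, ...) {
  cat("SBML import: document node", x$document_node, "\n")
  print(x$counts)
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  if (length(x$warnings)) cat(length(x$warnings), "warning(s)\n")
  invisible(x)
}
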