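# Post-import linking across data domains.
#
# (a) annotation RESOURCE -> ontology concept, by 7-character suffix match
#     between resource URI and concept id (the width of SBO/GO/KiSAO
#     accessions);
# (b) SED-ML model reference -> stored model, by resolving MODELSOURCE;
# (c) data-generator variable -> model entity, by its XPath target;
# (d) implicit cross-format entity links between models sharing a
#     reference publication, scored by name similarity and annotation
#     overlap. (a)-(c) are explicit links with confidence 1; (d) carries
#     its score as confidence.

edge_exists <- function(g, source, target, type) {
  any(vapply(pg_incident_edges(g, source, type, "out"),
             function(e) e$target == target, logical(1)))
}

#' Link annotation resources to imported ontology concepts
#'
#' For every `RESOURCE` node whose URI contains the ontology tag and whose
#' last `suffix_len` characters equal the last `suffix_len` characters of
#' a concept id, one `IS_ONTOLOGY_ENTRY` edge resource -> concept is
#' created, and the concept's label and definition are appended to the
#' resource's `RESOURCETEXT` (feeding the full-text index). A resource
#' whose suffix matches two concepts is an error, never a silent pick.
#' Re-running creates no duplicates.
#'
#' @param g A `property_graph`.
#' @param tag Tag of an imported ontology (see [import_ontology()]).
#' @param suffix_len Suffix width; 7 matches the zero-padded accessions of
#'   SBO, GO and KiSAO.
#' @return Number of links created.
#' @export
link_annotations_to_ontology <- function(g, tag, suffix_len = 7L) {
  reg <- ontology_registry(g)
  if (!exists(tag, envir = reg, inherits = FALSE))
    stop("no imported ontology with tag: ", tag)
  lab <- paste0(tag, "Ontology")
  concepts <- setdiff(pg_nodes_by_label(g, lab),
                      pg_nodes_by_label(g, "ONTOLOGY_ROOT"))
  csuffix <- vapply(concepts, function(n) {
    id <- pg_attr(g, n, "id")
    substring(id, max(1L, nchar(id) - suffix_len + 1L))
  }, character(1))
  created <- 0L
  for (res in pg_nodes_by_label(g, "RESOURCE")) {
    uri <- pg_attr(g, res, "URI")
    if (is.null(uri) || !grepl(tag, toupper(uri), fixed = TRUE)) next
    rsuffix <- substring(uri, max(1L, nchar(uri) - suffix_len + 1L))
    hits <- concepts[csuffix == rsuffix]
    if (length(hits) == 0L) next
    if (length(hits) > 1L)
      stop("resource ", uri, " suffix-matches multiple concepts: ",
           paste(vapply(hits, function(n) pg_attr(g, n, "id"),
                        character(1)), collapse = ", "))
    if (!edge_exists(g, res, hits, "IS_ONTOLOGY_ENTRY")) {
      pg_add_edge(g, res, hits, "IS_ONTOLOGY_ENTRY")
      txt <- paste(c(pg_attr(g, res, "RESOURCETEXT"),
                     pg_attr(g, hits, "NAME"),
                     pg_attr(g, hits, "DEFINITION")), collapse = " ")
      pg_set_attrs(g, res, list(RESOURCETEXT = trimws(txt)))
      created <- created + 1L
    }
  }
  created
}

# model documents resolvable by FILENAME, model ID, then basename
resolve_model_source <- function(g, source) {
  docs <- pg_nodes_by_label(g, "DOCUMENT")
  models <- lapply(docs, function(d) {
    ms <- intersect(pg_neighbors(g, d, "hasModel", "out"),
                    c(pg_nodes_by_label(g, "SBML_MODEL"),
                      pg_nodes_by_label(g, "CELLML_MODEL")))
    if (length(ms)) list(doc = d, model = ms[1],
                         filename = pg_attr(g, d, "FILENAME"),
                         model_id = pg_attr(g, ms[1], "ID"))
    else NULL
  })
  models <- Filter(Negate(is.null), models)
  pick <- function(f) Filter(f, models)
  hits <- pick(function(m) identical(m$filename, source))
  if (!length(hits)) hits <- pick(function(m) identical(m$model_id, source))
  if (!length(hits))
    hits <- pick(function(m) !is.null(m$filename) &&
                   basename(m$filename) == basename(source))
  hits
}

#' Link SED-ML model references to stored models
#'
#' Resolves every `SEDML_MODELREFERENCE` node's `MODELSOURCE` against the
#' stored model documents (exact filename, then model ID, then basename)
#' and adds a `REFERENCES_SIMULATION_MODEL` edge model reference -> model
#' node. Unresolved references are reported, not errors. Idempotent.
#'
#' @param g A `property_graph`.
#' @return List with `links` (data frame: link_type, source, target,
#'   edge_type, confidence, evidence) and `unresolved` (MODELSOURCE
#'   values that did not resolve, including ambiguous ones).
#' @export
link_sedml_to_models <- function(g) {
  rows <- list(); unresolved <- character()
  for (ref in pg_nodes_by_label(g, "SEDML_MODELREFERENCE")) {
    src <- pg_attr(g, ref, "MODELSOURCE")
    if (is.null(src)) { unresolved <- c(unresolved, "<missing source>"); next }
    hits <- resolve_model_source(g, src)
    if (length(hits) == 0L) { unresolved <- c(unresolved, src); next }
    if (length(hits) > 1L) {
      unresolved <- c(unresolved, paste0(src, " (ambiguous)")); next
    }
    m <- hits[[1]]$model
    if (!edge_exists(g, ref, m, "REFERENCES_SIMULATION_MODEL")) {
      pg_add_edge(g, ref, m, "REFERENCES_SIMULATION_MODEL")
      rows[[length(rows) + 1L]] <- link_record("b", ref, m,
        "REFERENCES_SIMULATION_MODEL", 1,
        paste0("model source resolved: ", src))
    }
  }
  list(links = bind_links(rows), unresolved = unresolved)
}

link_record <- function(type, source, target, edge_type, confidence, evidence) {
  data.frame(link_type = type, source = source, target = target,
             edge_type = edge_type, confidence = confidence,
             evidence = evidence, stringsAsFactors = FALSE)
}

bind_links <- function(rows) {
  if (length(rows)) do.call(rbind, rows)
  else data.frame(link_type = character(), source = integer(),
                  target = integer(), edge_type = character(),
                  confidence = numeric(), evidence = character())
}

# supported XPath subset: descendant selectors ending in an element with an
# @id/@name equality predicate, e.g.
#   /sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='CP']
#   //cellml:variable[@name='time']
parse_target_xpath <- function(xpath) {
  m <- regmatches(xpath,
    regexec("\\[\\s*@(id|name)\\s*=\\s*['\"]([^'\"]+)['\"]\\s*\\]\\s*$", xpath))[[1]]
  if (length(m) != 3L) return(NULL)
  list(attr = toupper(m[2]), value = m[3])
}

model_entities <- function(g, model) {
  fmt_labels <- c("SBML_SPECIES", "SBML_COMPARTMENT", "SBML_PARAMETER",
                  "SBML_REACTION", "CELLMLCOMPONENT", "CELLMLVARIABLE")
  ents <- integer()
  for (n in pg_neighbors(g, model, NULL, "out")) {
    if (any(pg_labels(g, n) %in% fmt_labels)) {
      ents <- c(ents, n)
      if ("CELLMLCOMPONENT" %in% pg_labels(g, n))
        ents <- c(ents, pg_neighbors(g, n, "hasVariable", "out"))
    }
  }
  sort(unique(ents))
}

#' Link data-generator variables to the model entities they observe
#'
#' Requires [link_sedml_to_models()] to have run, so targets resolve
#' within the referenced models. Every `SEDML_VARIABLE` whose XPath
#' target names an entity (by `@id` or `@name`) in a linked model gains
#' an `OBSERVES` edge variable -> entity; every change element whose
#' target names a species flags that species with `IS_CHANGED = TRUE`.
#' XPath expressions outside the supported subset are reported as
#' unresolved. Idempotent.
#'
#' @param g A `property_graph`.
#' @return List with `links` (data frame as in [link_sedml_to_models()])
#'   and `unresolved` (targets that could not be resolved).
#' @export
link_datagenerators_to_entities <- function(g) {
  rows <- list(); unresolved <- character()
  find_entity <- function(models, key, value) {
    for (m in models) {
      for (e in model_entities(g, m)) {
        v <- pg_attr(g, e, key)
        if (identical(v, value)) return(e)
        if (key == "ID" && identical(pg_attr(g, e, "NAME"), value)) return(e)
      }
    }
    NULL
  }
  linked_models_of_doc <- function(sed_doc, ref_id = NULL) {
    if (length(sed_doc) != 1L) return(integer())
    anchor <- pg_neighbors(g, sed_doc, "hasSedml", "out")
    if (length(anchor) != 1L) return(integer())
    refs <- pg_neighbors(g, anchor, "hasModelReference", "out")
    if (!is.null(ref_id))
      refs <- Filter(function(r) identical(pg_attr(g, r, "ID"), ref_id),
                     refs)
    unlist(lapply(refs, function(r)
      pg_neighbors(g, r, "REFERENCES_SIMULATION_MODEL", "out")))
  }
  for (v in pg_nodes_by_label(g, "SEDML_VARIABLE")) {
    tgt <- pg_attr(g, v, "TARGET")
    if (is.null(tgt)) next
    parsed <- parse_target_xpath(tgt)
    if (is.null(parsed)) { unresolved <- c(unresolved, tgt); next }
    doc <- pg_traverse(g, v, "BELONGS_TO", "out", 1L, Inf)
    doc <- intersect(doc, pg_nodes_by_label(g, "DOCUMENT"))
    # a variable's task names its model reference; restrict resolution to
    # that model when known
    mref <- pg_attr(g, v, "MODELREF")
    models <- linked_models_of_doc(doc, mref)
    ent <- find_entity(models, if (parsed$attr == "ID") "ID" else "NAME",
                       parsed$value)
    if (is.null(ent) && parsed$attr == "NAME")
      ent <- find_entity(models, "ID", parsed$value)
    if (is.null(ent)) { unresolved <- c(unresolved, tgt); next }
    if (!edge_exists(g, v, ent, "OBSERVES")) {
      pg_add_edge(g, v, ent, "OBSERVES")
      rows[[length(rows) + 1L]] <- link_record("c", v, ent, "OBSERVES", 1,
        paste0("target resolved: ", tgt))
    }
  }
  for (ch in pg_nodes_by_label(g, "SEDML_CHANGE")) {
    tgt <- pg_attr(g, ch, "TARGET")
    parsed <- if (is.null(tgt)) NULL else parse_target_xpath(tgt)
    if (is.null(parsed)) { if (!is.null(tgt)) unresolved <- c(unresolved, tgt); next }
    ref <- pg_neighbors(g, ch, "BELONGS_TO", "out")
    models <- unlist(lapply(ref, function(r)
      pg_neighbors(g, r, "REFERENCES_SIMULATION_MODEL", "out")))
    ent <- find_entity(models, if (parsed$attr == "ID") "ID" else "NAME",
                       parsed$value)
    if (!is.null(ent)) pg_set_attrs(g, ent, list(IS_CHANGED = TRUE))
    else unresolved <- c(unresolved, tgt)
  }
  list(links = bind_links(rows), unresolved = unresolved)
}

# light Porter-style suffix stripping: enough to make plural/participle
# variants of entity names comparable; short tokens pass through untouched
stem_token <- function(w) {
  if (nchar(w) > 4) {
    if (grepl("sses$", w)) w <- sub("sses$", "ss", w)
    else if (grepl("ies$", w)) w <- sub("ies$", "i", w)
    else if (grepl("[^s]s$", w)) w <- sub("s$", "", w)
  }
  if (nchar(w) > 5 && grepl("ing$", w)) w <- sub("ing$", "", w)
  else if (nchar(w) > 4 && grepl("ed$", w)) w <- sub("ed$", "", w)
  w
}

normalize_name <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  paste(vapply(toks[nzchar(toks)], stem_token, character(1)), collapse = " ")
}

#' Name similarity between two entity names
#'
#' `1 - d / max(nchar)` where `d` is the Levenshtein distance between the
#' case-folded, lightly stemmed names.
#' @param a,b Entity names.
#' @return Similarity in `[0, 1]`.
#' @export
name_similarity <- function(a, b) {
  na <- normalize_name(a); nb <- normalize_name(b)
  if (!nzchar(na) && !nzchar(nb)) return(1)
  d <- utils::adist(na, nb)[1, 1]
  1 - d / max(nchar(na), nchar(nb))
}

entity_annotation_keys <- function(g, ent) {
  keys <- character()
  for (ann in pg_neighbors(g, ent, "hasAnnotation", "out")) {
    for (e in pg_incident_edges(g, ann, NULL, "out")) {
      if (e$type %in% c("BELONGS_TO")) next
      tl <- pg_labels(g, e$target)
      if ("RESOURCE" %in% tl && !("PUBLICATION" %in% tl))
        keys <- c(keys, pg_attr(g, e$target, "KEY"))
    }
  }
  unique(keys)
}

model_publications <- function(g, model) {
  keys <- character()
  for (ann in pg_neighbors(g, model, "hasAnnotation", "out")) {
    for (res in pg_neighbors(g, ann, NULL, "out")) {
      if ("PUBLICATION" %in% pg_labels(g, res))
        keys <- c(keys, pg_attr(g, res, "KEY"))
    }
  }
  unique(keys)
}

#' Infer implicit cross-format entity links
#'
#' For every pair of one SBML and one CellML model that share a reference
#' publication, every cross-product pair of named entities (SBML species,
#' compartments and parameters against CellML components and variables)
#' is scored as `w_name * sim + w_ann * ann`, where `sim` is the
#' Levenshtein name similarity ([name_similarity()]) and `ann` is 1 when
#' the two entities share at least one normalized annotation resource.
#' Pairs scoring at or above `threshold` become `IS_SIMILAR_TO` edges
#' (confidence attribute = score); each entity keeps only its
#' best-scoring counterpart (ties broken lexicographically by counterpart
#' name) and the symmetric edge is stored once. Models without a shared
#' publication are never linked, whatever the names. Idempotent.
#'
#' @param g A `property_graph`.
#' @param threshold Minimum score in `[0, 1]` for a link (default 0.7).
#' @param weights Two non-negative weights `(name, annotation)` summing
#'   to 1; default `c(0.7, 0.3)`.
#' @return Data frame of link records (`link_type = "d"`, endpoints,
#'   confidence, evidence).
#' @export
infer_cross_format_links <- function(g, threshold = 0.7,
                                     weights = c(0.7, 0.3)) {
  stopifnot(threshold >= 0, threshold <= 1,
            length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  sbml_models <- pg_nodes_by_label(g, "SBML_MODEL")
  cellml_models <- pg_nodes_by_label(g, "CELLML_MODEL")
  rows <- list()
  ent_name <- function(e) {
    nm <- pg_attr(g, e, "NAME")
    if (is.null(nm)) pg_attr(g, e, "ID") else nm
  }
  named_entities <- function(model, labels) {
    ents <- model_entities(g, model)
    ents <- Filter(function(e) any(pg_labels(g, e) %in% labels) &&
                     !is.null(ent_name(e)), ents)
    ents
  }
  for (sm in sbml_models) {
    pubs_s <- model_publications(g, sm)
    if (!length(pubs_s)) next
    for (cm in cellml_models) {
      shared <- intersect(pubs_s, model_publications(g, cm))
      if (!length(shared)) next
      left <- named_entities(sm, c("SBML_SPECIES", "SBML_COMPARTMENT",
                                   "SBML_PARAMETER"))
      right <- named_entities(cm, c("CELLMLCOMPONENT", "CELLMLVARIABLE"))
      if (!length(left) || !length(right)) next
      ann_l <- lapply(left, function(e) entity_annotation_keys(g, e))
      ann_r <- lapply(right, function(e) entity_annotation_keys(g, e))
      score <- matrix(0, length(left), length(right))
      for (i in seq_along(left)) for (j in seq_along(right)) {
        sim <- name_similarity(ent_name(left[i]), ent_name(right[j]))
        ann <- as.numeric(length(intersect(ann_l[[i]], ann_r[[j]])) > 0)
        score[i, j] <- weights[1] * sim + weights[2] * ann
      }
      keep <- matrix(FALSE, length(left), length(right))
      best_of <- function(scores, names_) {
        ok <- which(scores >= threshold)
        if (!length(ok)) return(integer())
        top <- ok[scores[ok] == max(scores[ok])]
        top[order(names_[top])][1]
      }
      rnames <- vapply(right, ent_name, character(1))
      lnames <- vapply(left, ent_name, character(1))
      for (i in seq_along(left)) {
        j <- best_of(score[i, ], rnames)
        if (length(j)) keep[i, j] <- TRUE
      }
      for (j in seq_along(right)) {
        i <- best_of(score[, j], lnames)
        if (length(i)) keep[i, j] <- TRUE
      }
      for (i in seq_along(left)) for (j in seq_along(right)) {
        if (!keep[i, j]) next
        a <- left[i]; b <- right[j]
        if (edge_exists(g, a, b, "IS_SIMILAR_TO") ||
            edge_exists(g, b, a, "IS_SIMILAR_TO")) next
        sim <- name_similarity(lnames[i], rnames[j])
        ann <- length(intersect(ann_l[[i]], ann_r[[j]])) > 0
        pg_add_edge(g, a, b, "IS_SIMILAR_TO",
                    list(confidence = score[i, j]))
        rows[[length(rows) + 1L]] <- link_record("d", a, b, "IS_SIMILAR_TO",
          score[i, j],
          paste0("shared publication + levenshtein ", round(sim, 2),
                 if (ann) " + shared annotation" else ""))
      }
    }
  }
  bind_links(rows)
}
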