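# Pattern matching, aggregation, full-text ranking and the canned queries.
#
# The query layer is a programmatic pattern API plus named canned queries
# (no text query-language parser): patterns are lists of steps, evaluated
# by index-seeded traversal, with deterministic row order.

#' Construct a pattern step
#'
#' A pattern is a non-empty list of steps. The first step selects start
#' nodes by label and attribute filters; each later step extends every
#' binding along edges of `edge_type` (`NULL` = wildcard) in `direction`
#' with hop bounds, then filters by `label` and `filters`. A negated step
#' asserts absence and binds no variable.
#'
#' @param label Node label to require, or `NULL`.
#' @param var Variable name for the bound node (default `v1`, `v2`, ...).
#' @param filters List of `list(attr, op, value)` with `op` one of
#'   `"equals"`, `"regex"` (unanchored, case-sensitive), `"contains"`.
#' @param edge_type Edge type for the hop into this step (`NULL` = any).
#' @param direction `"out"`, `"in"` or `"both"`.
#' @param min_hops,max_hops Hop bounds (`max_hops = Inf` for `*`).
#' @param negated Assert that no such extension exists.
#' @return A pattern step (list).
#' @export
p_step <- function(label = NULL, var = NULL, filters = list(),
                   edge_type = NULL, direction = "out",
                   min_hops = 1L, max_hops = min_hops, negated = FALSE) {
  if (min_hops < 0 || min_hops > max_hops)
    stop("invalid hop bounds: need 0 <= min_hops <= max_hops")
  list(label = label, var = var, filters = filters, edge_type = edge_type,
       direction = match.arg(direction, c("out", "in", "both")),
       min_hops = min_hops, max_hops = max_hops, negated = negated)
}

#' Attribute filter for a pattern step
#' @param attr Attribute name.
#' @param op `"equals"`, `"regex"` or `"contains"`.
#' @param value Comparison value.
#' @return A filter (list) for [p_step()].
#' @export
p_filter <- function(attr, op, value) {
  list(attr = attr, op = match.arg(op, c("equals", "regex", "contains")),
       value = value)
}

node_passes <- function(g, id, label, filters) {
  if (!is.null(label) && !(label %in% pg_labels(g, id))) return(FALSE)
  for (f in filters) {
    v <- pg_attr(g, id, f$attr)
    if (is.null(v)) return(FALSE)
    v <- as.character(v)
    ok <- switch(f$op,
      equals = identical(v, as.character(f$value)),
      regex = grepl(f$value, v),
      contains = grepl(f$value, v, fixed = TRUE))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Evaluate a graph pattern
#'
#' @param g A `property_graph`.
#' @param pattern Non-empty list of [p_step()]s.
#' @return Data frame of bindings: one column of node ids per non-negated
#'   step, rows sorted by node ids (deterministic).
#' @export
pg_match <- function(g, pattern) {
  if (!length(pattern)) stop("pattern must not be empty")
  if (isTRUE(pattern[[1]]$negated))
    stop("the first pattern step cannot be negated")
  vars <- character(); k <- 0L
  for (i in seq_along(pattern)) {
    if (!pattern[[i]]$negated) {
      k <- k + 1L
      vars <- c(vars, if (is.null(pattern[[i]]$var))
        paste0("v", k) else pattern[[i]]$var)
    }
  }
  s1 <- pattern[[1]]
  starts <- if (!is.null(s1$label)) pg_nodes_by_label(g, s1$label)
            else seq_len(pg_node_count(g))
  starts <- starts[vapply(starts, function(id)
    node_passes(g, id, s1$label, s1$filters), logical(1))]
  rows <- lapply(starts, function(s) s)
  for (i in seq_along(pattern)[-1]) {
    st <- pattern[[i]]
    new_rows <- list()
    for (row in rows) {
      anchor <- row[length(row)]
      cand <- pg_traverse(g, anchor, st$edge_type, st$direction,
                          st$min_hops, st$max_hops)
      cand <- cand[vapply(cand, function(id)
        node_passes(g, id, st$label, st$filters), logical(1))]
      cand <- setdiff(cand, row)   # simple paths: no node reused in a row
      if (st$negated) {
        if (length(cand) == 0L)
          new_rows[[length(new_rows) + 1L]] <- row
      } else {
        for (c_ in cand)
          new_rows[[length(new_rows) + 1L]] <- c(row, c_)
      }
    }
    rows <- new_rows
  }
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      rep(list(integer()), length(vars)), vars))
    return(out)
  }
  m <- do.call(rbind, rows)
  out <- as.data.frame(m)
  names(out) <- vars
  out[do.call(order, out), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Grouped aggregation over pattern-match rows
#'
#' Supports `count`, `min`, `max`, `avg`, `stdev` (sample, n-1
#' denominator) and `collect` (sorted distinct values), with optional
#' `ORDER BY` / `LIMIT` semantics.
#'
#' @param rows Data frame (bindings or scalars).
#' @param group_by Character vector of grouping columns (may be empty).
#' @param aggregates Named list; each element `list(fun, var)` with `fun`
#'   in `count|min|max|avg|stdev|collect`. `var` may be omitted for
#'   `count`.
#' @param order_by Column to order the result by.
#' @param descending Order direction.
#' @param limit Maximum number of result rows.
#' @return Data frame with one row per group.
#' @export
pg_aggregate <- function(rows, group_by = character(), aggregates = list(),
                         order_by = NULL, descending = FALSE, limit = NULL) {
  for (col in c(group_by, unlist(lapply(aggregates, `[[`, "var"))))
    if (!is.null(col) && !(col %in% names(rows)))
      stop("aggregate over unbound variable: ", col)
  groups <- if (length(group_by))
    split(rows, interaction(rows[group_by], drop = TRUE, lex.order = TRUE))
  else list(all = rows)
  out <- lapply(groups, function(gr) {
    res <- if (length(group_by)) gr[1, group_by, drop = FALSE]
           else data.frame(row.names = 1)
    for (nm in names(aggregates)) {
      a <- aggregates[[nm]]
      v <- if (!is.null(a$var)) gr[[a$var]] else NULL
      res[[nm]] <- switch(a$fun,
        count = if (is.null(v)) nrow(gr) else length(v[!is.na(v)]),
        min = min(v), max = max(v), avg = mean(v),
        stdev = stats::sd(v),
        collect = I(list(sort(unique(v)))),
        stop("unknown aggregate: ", a$fun))
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (length(group_by))
    out <- out[do.call(order, out[group_by]), , drop = FALSE]
  if (!is.null(order_by)) {
    o <- order(out[[order_by]], decreasing = descending)
    # deterministic tie-break: remaining columns in order
    tie <- setdiff(names(out), order_by)
    tie <- tie[!vapply(out[tie], is.list, logical(1))]
    if (length(tie))
      o <- do.call(order, c(list(if (descending) -xtfrm(out[[order_by]])
                                 else xtfrm(out[[order_by]])),
                            lapply(out[tie], xtfrm)))
    out <- out[o, , drop = FALSE]
  }
  if (!is.null(limit)) out <- utils::head(out, limit)
  rownames(out) <- NULL
  out
}

tokenize_text <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

text_index <- function(g) {
  if (!is.null(g$text_cache) && g$text_cache$stamp == g$mutations)
    return(g$text_cache)
  docs <- list(); uris <- character(); ids <- integer()
  for (r in pg_nodes_by_label(g, "RESOURCE")) {
    txt <- pg_attr(g, r, "RESOURCETEXT")
    if (is.null(txt) || !nzchar(txt)) next
    ids <- c(ids, r)
    uris <- c(uris, as.character(pg_attr(g, r, "URI")))
    docs[[length(docs) + 1L]] <- tokenize_text(txt)
  }
  df <- new.env(parent = emptyenv())
  for (d in docs) for (tok in unique(d)) {
    cur <- if (exists(tok, envir = df, inherits = FALSE))
      get(tok, envir = df) else 0L
    assign(tok, cur + 1L, envir = df)
  }
  g$text_cache <- list(stamp = g$mutations, ids = ids, uris = uris,
                       docs = docs, df = df, n = length(docs))
  g$text_cache
}

#' Ranked full-text search over resource descriptions
#'
#' Conjunctive token search over the `RESOURCETEXT` of all RESOURCE
#' nodes (case-insensitive, tokenized on non-alphanumerics): a resource
#' matches when it contains every query token, and matches are ranked by
#' a TF-IDF score (log-scaled term frequency `1 + log tf`, inverse
#' document frequency `log(N/df)`), ties broken by URI.
#'
#' @param g A `property_graph`.
#' @param query Query text; must contain at least one token.
#' @return Data frame `node`, `URI`, `score`, ranked by descending score.
#' @export
text_search <- function(g, query) {
  qtoks <- unique(tokenize_text(query))
  if (!length(qtoks)) stop("empty text query")
  ix <- text_index(g)
  if (ix$n == 0L)
    return(data.frame(node = integer(), URI = character(),
                      score = numeric()))
  rows <- list()
  for (i in seq_len(ix$n)) {
    d <- ix$docs[[i]]
    if (!all(qtoks %in% d)) next
    score <- 0
    for (tok in qtoks) {
      tf <- sum(d == tok)
      df <- get(tok, envir = ix$df)
      score <- score + (1 + log(tf)) * log(ix$n / df)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      node = ix$ids[i], URI = ix$uris[i], score = score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(node = integer(), URI = character(),
                      score = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$URI), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- canned queries -------------------------------------------------------

models_of_element <- function(g, e, label) {
  intersect(pg_neighbors(g, e, "BELONGS_TO", "out"),
            pg_nodes_by_label(g, label))
}

chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)

CANNED_QUERIES <- c(
  "species_only_modifier_top", "simulations_for_model",
  "models_by_algorithm", "experiments_observing", "top_annotations",
  "annotation_count_with_descendants", "annotation_stats_per_model",
  "list_species", "element_annotations", "elements_annotated_with",
  "list_models_by_format", "model_by_name", "list_components",
  "count_variables", "variables_per_component_stats",
  "annotation_index_lookup")

#' Run one of the registered canned queries
#'
#' Composed pattern + aggregation queries covering structural look-ups,
#' cross-domain retrieval, statistics and index search:
#' \describe{
#'   \item{species_only_modifier_top}{Species acting only as modifiers,
#'     top model by modifier count (`n` results, default 1).}
#'   \item{simulations_for_model}{All simulation descriptions applicable
#'     to the model named `name`.}
#'   \item{models_by_algorithm}{Models (label `format`, default
#'     `CELLML_MODEL`) simulable with algorithm `kisao`.}
#'   \item{experiments_observing}{Simulation experiments observing a
#'     species annotated (`qualifier`, default `is`) with a resource
#'     matching the indexed `phrase`, where the species has reaction role
#'     `role` (default `IS_MODIFIER`).}
#'   \item{top_annotations}{The `n` most used annotation resources.}
#'   \item{annotation_count_with_descendants}{Annotations pointing to
#'     `concept` or any of its isA descendants (returns total + direct).}
#'   \item{annotation_stats_per_model}{Min/max/avg/stdev of annotations
#'     per model (label param, default `SBML_MODEL`).}
#'   \item{list_species}{Species ids/names of model with ID `model`.}
#'   \item{element_annotations}{Element-level annotations of model with
#'     ID `model`.}
#'   \item{elements_annotated_with}{All elements whose annotation URI
#'     matches `regex`, with qualifier and model.}
#'   \item{list_models_by_format}{All models carrying label `format`.}
#'   \item{model_by_name}{Models with NAME `name` (label `format`).}
#'   \item{list_components}{Component names of CellML model `name`.}
#'   \item{count_variables}{Number of variables of CellML model `name`.}
#'   \item{variables_per_component_stats}{Min/max/avg/stdev of variables
#'     per CellML component.}
#'   \item{annotation_index_lookup}{Ranked index search for `phrase`.}
#' }
#'
#' @param g A `property_graph`.
#' @param name Canned query name (see above).
#' @param params Named list of parameters.
#' @return A data frame (most queries) or a named list of aggregates.
#' @export
canned_query <- function(g, name, params = list()) {
  if (!(name %in% CANNED_QUERIES))
    stop("unknown canned query '", name, "'; valid names: ",
         paste(CANNED_QUERIES, collapse = ", "))
  p <- function(key, default = NULL) {
    if (!is.null(params[[key]])) params[[key]] else default
  }
  switch(name,
    species_only_modifier_top = {
      rows <- list()
      for (s in pg_nodes_by_label(g, "SBML_SPECIES")) {
        nmod <- length(pg_incident_edges(g, s, "IS_MODIFIER", "out"))
        if (nmod == 0L) next
        if (length(pg_incident_edges(g, s, "IS_REACTANT", "out")) ||
            length(pg_incident_edges(g, s, "IS_PRODUCT", "out"))) next
        m <- models_of_element(g, s, "SBML_MODEL")
        rows[[length(rows) + 1L]] <- data.frame(
          Model = chr_or_na(pg_attr(g, m[1], "NAME")),
          Species = chr_or_na(pg_attr(g, s, "NAME")),
          numOfMod = nmod, stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, c(rows, list(data.frame(
        Model = character(), Species = character(),
        numOfMod = integer()))))
      out <- out[order(-out$numOfMod, out$Species), , drop = FALSE]
      rownames(out) <- NULL
      utils::head(out, p("n", 1L))
    },
    simulations_for_model = {
      nm <- p("name"); stopifnot(!is.null(nm))
      rows <- list()
      models <- c(pg_nodes_by_label(g, "SBML_MODEL"),
                  pg_nodes_by_label(g, "CELLML_MODEL"))
      for (m in models) {
        if (!identical(pg_attr(g, m, "NAME"), nm)) next
        for (ref in pg_neighbors(g, m, "REFERENCES_SIMULATION_MODEL", "in")) {
          docs <- intersect(pg_traverse(g, ref, "BELONGS_TO", "out", 2L, 2L),
                            pg_nodes_by_label(g, "DOCUMENT"))
          for (d in docs)
            rows[[length(rows) + 1L]] <- data.frame(
              Model = nm, ModelID = chr_or_na(pg_attr(g, m, "ID")),
              ModelSource = chr_or_na(pg_attr(g, ref, "MODELSOURCE")),
              SEDMLFile = chr_or_na(pg_attr(g, d, "FILENAME")),
              stringsAsFactors = FALSE)
        }
      }
      sorted_unique_rows(rows, c("Model", "ModelID", "ModelSource",
                                 "SEDMLFile"))
    },
    models_by_algorithm = {
      kisao <- p("kisao"); stopifnot(!is.null(kisao))
      fmt <- p("format", "CELLML_MODEL")
      rows <- list()
      for (sim in pg_nodes_by_label(g, "SEDML_SIMULATION")) {
        if (!identical(pg_attr(g, sim, "SIMKISAO"), kisao)) next
        docs <- intersect(pg_traverse(g, sim, "BELONGS_TO", "out", 2L, 2L),
                          pg_nodes_by_label(g, "DOCUMENT"))
        for (ref in pg_neighbors(g, sim, "SIMULATES", "out")) {
          for (m in pg_neighbors(g, ref, "REFERENCES_SIMULATION_MODEL", "out")) {
            if (!(fmt %in% pg_labels(g, m))) next
            for (d in docs)
              rows[[length(rows) + 1L]] <- data.frame(
                Model = chr_or_na(pg_attr(g, m, "NAME")),
                SEDMLFile = chr_or_na(pg_attr(g, d, "FILENAME")),
                stringsAsFactors = FALSE)
          }
        }
      }
      sorted_unique_rows(rows, c("Model", "SEDMLFile"))
    },
    experiments_observing = {
      phrase <- p("phrase"); stopifnot(!is.null(phrase))
      qual <- p("qualifier", "is"); role <- p("role", "IS_MODIFIER")
      hits <- text_search(g, phrase)
      rows <- list()
      for (res in hits$node) {
        anns <- vapply(Filter(function(e) e$type == qual,
                              pg_incident_edges(g, res, NULL, "in")),
                       function(e) e$source, integer(1))
        anns <- intersect(anns, pg_nodes_by_label(g, "ANNOTATION"))
        for (ann in anns) {
          sps <- intersect(pg_neighbors(g, ann, "BELONGS_TO", "out"),
                           pg_nodes_by_label(g, "SBML_SPECIES"))
          for (s in sps) {
            if (!length(pg_incident_edges(g, s, role, "out"))) next
            obs <- intersect(pg_neighbors(g, s, "OBSERVES", "in"),
                             pg_nodes_by_label(g, "SEDML_VARIABLE"))
            m <- models_of_element(g, s, "SBML_MODEL")
            for (o in obs) {
              docs <- intersect(
                pg_traverse(g, o, "BELONGS_TO", "out", 1L, Inf),
                pg_nodes_by_label(g, "DOCUMENT"))
              for (d in docs)
                rows[[length(rows) + 1L]] <- data.frame(
                  SEDML = chr_or_na(pg_attr(g, d, "FILENAME")),
                  Model = chr_or_na(pg_attr(g, m[1], "NAME")),
                  Resource = chr_or_na(pg_attr(g, res, "URI")),
                  Species = chr_or_na(pg_attr(g, s, "NAME")),
                  Target = chr_or_na(pg_attr(g, o, "TARGET")),
                  stringsAsFactors = FALSE)
            }
          }
        }
      }
      sorted_unique_rows(rows, c("SEDML", "Model", "Resource", "Species",
                                 "Target"))
    },
    top_annotations = {
      n <- p("n", 3L)
      rows <- list()
      for (r in pg_nodes_by_label(g, "RESOURCE")) {
        cnt <- length(pg_incident_edges(g, r, "BELONGS_TO", "out"))
        if (cnt == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          Annotation = chr_or_na(pg_attr(g, r, "URI")),
          AnnotationCount = cnt, stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, c(rows, list(data.frame(
        Annotation = character(), AnnotationCount = integer()))))
      out <- out[order(-out$AnnotationCount, out$Annotation), , drop = FALSE]
      rownames(out) <- NULL
      utils::head(out, n)
    },
    annotation_count_with_descendants = {
      concept <- p("concept"); stopifnot(!is.null(concept))
      closure <- descendants(g, concept)
      direct_id <- pg_attr(g, concept_node(g, concept), "id")
      total <- 0L; direct <- 0L
      for (cid in closure) {
        cn <- concept_node(g, cid)
        for (res in pg_neighbors(g, cn, "IS_ONTOLOGY_ENTRY", "in")) {
          cnt <- length(pg_incident_edges(g, res, NULL, "in"))
          total <- total + cnt
          if (identical(cid, direct_id)) direct <- direct + cnt
        }
      }
      list(total = total, direct = direct)
    },
    annotation_stats_per_model = {
      label <- p("label", "SBML_MODEL")
      counts <- integer()
      for (m in pg_nodes_by_label(g, label)) {
        anns <- intersect(pg_traverse(g, m, "BELONGS_TO", "in", 1L, 2L),
                          pg_nodes_by_label(g, "ANNOTATION"))
        n <- 0L
        for (ann in anns)
          n <- n + sum(vapply(pg_incident_edges(g, ann, "BELONGS_TO", "in"),
                              function(e) "RESOURCE" %in% pg_labels(g, e$source),
                              logical(1)))
        if (n > 0L) counts <- c(counts, n)
      }
      if (!length(counts))
        return(list(max = NA, min = NA, avg = NA, stdev = NA, n_models = 0L))
      list(max = max(counts), min = min(counts), avg = mean(counts),
           stdev = stats::sd(counts), n_models = length(counts))
    },
    list_species = {
      mid <- p("model"); stopifnot(!is.null(mid))
      rows <- list()
      for (m in pg_nodes_by_label(g, "SBML_MODEL")) {
        if (!identical(pg_attr(g, m, "ID"), mid) &&
            !identical(pg_attr(g, m, "NAME"), mid)) next
        for (s in pg_neighbors(g, m, "hasSpecies", "out"))
          rows[[length(rows) + 1L]] <- data.frame(
            SpeciesID = chr_or_na(pg_attr(g, s, "ID")),
            SpeciesName = chr_or_na(pg_attr(g, s, "NAME")),
            stringsAsFactors = FALSE)
      }
      sorted_unique_rows(rows, c("SpeciesID", "SpeciesName"))
    },
    element_annotations = {
      mid <- p("model"); stopifnot(!is.null(mid))
      rows <- list()
      for (m in pg_nodes_by_label(g, "SBML_MODEL")) {
        if (!identical(pg_attr(g, m, "ID"), mid)) next
        for (e in pg_neighbors(g, m, "BELONGS_TO", "in")) {
          for (ann in pg_neighbors(g, e, "hasAnnotation", "out")) {
            ress <- intersect(pg_neighbors(g, ann, NULL, "out"),
                              pg_nodes_by_label(g, "RESOURCE"))
            for (r in ress)
              rows[[length(rows) + 1L]] <- data.frame(
                Element = chr_or_na(pg_attr(g, e, "ID")),
                ElementType = pg_labels(g, e)[1],
                Annotation = chr_or_na(pg_attr(g, r, "URI")),
                stringsAsFactors = FALSE)
          }
        }
      }
      sorted_unique_rows(rows, c("Element", "ElementType", "Annotation"))
    },
    elements_annotated_with = {
      regex <- p("regex"); stopifnot(!is.null(regex))
      rows <- list()
      for (r in pg_nodes_by_label(g, "RESOURCE")) {
        uri <- chr_or_na(pg_attr(g, r, "URI"))
        if (is.na(uri) || !grepl(regex, uri)) next
        for (qe in pg_incident_edges(g, r, NULL, "in")) {
          ann <- qe$source
          if (!("ANNOTATION" %in% pg_labels(g, ann))) next
          for (el in pg_neighbors(g, ann, "BELONGS_TO", "out")) {
            models <- c(models_of_element(g, el, "SBML_MODEL"),
                        models_of_element(g, el, "CELLML_MODEL"))
            if (!length(models)) next
            rows[[length(rows) + 1L]] <- data.frame(
              ModelID = chr_or_na(pg_attr(g, models[1], "ID")),
              ElementID = chr_or_na(pg_attr(g, el, "ID")),
              Qualifier = qe$type, URI = uri,
              stringsAsFactors = FALSE)
          }
        }
      }
      sorted_unique_rows(rows, c("ModelID", "ElementID", "Qualifier", "URI"))
    },
    list_models_by_format = {
      fmt <- p("format", "CELLML_MODEL")
      rows <- lapply(pg_nodes_by_label(g, fmt), function(m) data.frame(
        node = m, Name = chr_or_na(pg_attr(g, m, "NAME")),
        ID = chr_or_na(pg_attr(g, m, "ID")), stringsAsFactors = FALSE))
      out <- do.call(rbind, c(rows, list(data.frame(
        node = integer(), Name = character(), ID = character()))))
      rownames(out) <- NULL
      out
    },
    model_by_name = {
      nm <- p("name"); stopifnot(!is.null(nm))
      fmt <- p("format", "CELLML_MODEL")
      rows <- list()
      for (m in pg_nodes_by_label(g, fmt))
        if (identical(pg_attr(g, m, "NAME"), nm))
          rows[[length(rows) + 1L]] <- data.frame(
            node = m, Name = nm, stringsAsFactors = FALSE)
      do.call(rbind, c(rows, list(data.frame(node = integer(),
                                             Name = character()))))
    },
    list_components = {
      nm <- p("name"); stopifnot(!is.null(nm))
      rows <- list()
      for (m in pg_nodes_by_label(g, "CELLML_MODEL")) {
        if (!identical(pg_attr(g, m, "NAME"), nm)) next
        for (c_ in pg_neighbors(g, m, "hasComponent", "out"))
          rows[[length(rows) + 1L]] <- data.frame(
            Component = chr_or_na(pg_attr(g, c_, "NAME")),
            stringsAsFactors = FALSE)
      }
      sorted_unique_rows(rows, "Component")
    },
    count_variables = {
      nm <- p("name"); stopifnot(!is.null(nm))
      n <- 0L
      for (m in pg_nodes_by_label(g, "CELLML_MODEL")) {
        if (!identical(pg_attr(g, m, "NAME"), nm)) next
        for (c_ in pg_neighbors(g, m, "hasComponent", "out"))
          n <- n + length(pg_neighbors(g, c_, "hasVariable", "out"))
      }
      n
    },
    variables_per_component_stats = {
      counts <- vapply(pg_nodes_by_label(g, "CELLMLCOMPONENT"),
                       function(c_) length(pg_neighbors(g, c_, "hasVariable",
                                                        "out")),
                       integer(1))
      if (!length(counts))
        return(list(min = NA, max = NA, avg = NA, stdev = NA,
                    n_components = 0L))
      list(min = min(counts), max = max(counts), avg = mean(counts),
           stdev = stats::sd(counts), n_components = length(counts))
    },
    annotation_index_lookup = {
      phrase <- p("phrase"); stopifnot(!is.null(phrase))
      text_search(g, phrase)
    })
}

sorted_unique_rows <- function(rows, cols) {
  out <- do.call(rbind, c(rows, list(as.data.frame(stats::setNames(
    rep(list(character()), length(cols)), cols)))))
  out <- unique(out)
  if (nrow(out)) out <- out[do.call(order, out[cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
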