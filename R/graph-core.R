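#' Create an empty property graph
#'
#' The property graph is the single store all importers write into: labelled
#' nodes carrying attribute maps, typed directed edges, plus a label index,
#' an attribute index and a full-text index over resource description text.
#' The store is a mutable environment; all `pg_*` functions modify it in
#' place and node identifiers are store-assigned monotonically increasing
#' integers, stable within a session but not across re-imports.
#'
#' @return A `property_graph` object.
#' @examples
#' g <- pg_new()
#' n <- pg_add_node(g, "SBML_SPECIES", list(ID = "pM"))
#' pg_nodes_by_label(g, "SBML_SPECIES")
#' @export
pg_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- new.env(parent = emptyenv())
  g$edges <- new.env(parent = emptyenv())
  g$out <- new.env(parent = emptyenv())
  g$inc <- new.env(parent = emptyenv())
  g$label_index <- new.env(parent = emptyenv())
  g$next_node <- 1L
  g$next_edge <- 1L
  g$mutations <- 0L
  g$text_cache <- NULL
  class(g) <- "property_graph"
  g
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph: %d nodes, %d edges, %d labels>\n",
              pg_node_count(x), pg_edge_count(x),
              length(ls(x$label_index))))
  invisible(x)
}

#' Number of nodes / edges in a store
#' @param g A `property_graph`.
#' @return Integer count.
#' @export
pg_node_count <- function(g) g$next_node - 1L

#' @rdname pg_node_count
#' @export
pg_edge_count <- function(g) g$next_edge - 1L

#' Add a node to a property graph
#'
#' @param g A `property_graph`.
#' @param labels Character vector of labels; must be non-empty.
#' @param attrs Named list of scalar attributes (text or number).
#' @return The new node id (integer).
#' @export
pg_add_node <- function(g, labels, attrs = list()) {
  labels <- unique(as.character(labels))
  if (length(labels) == 0L || any(!nzchar(labels)))
    stop("a node needs at least one non-empty label")
  if (length(attrs) && (is.null(names(attrs)) || any(!nzchar(names(attrs)))))
    stop("attributes must be named")
  id <- g$next_node
  g$next_node <- id + 1L
  assign(as.character(id), list(id = id, labels = labels, attrs = attrs),
         envir = g$nodes)
  for (lab in labels) {
    cur <- if (exists(lab, envir = g$label_index, inherits = FALSE))
      get(lab, envir = g$label_index) else integer()
    assign(lab, c(cur, id), envir = g$label_index)
  }
  g$mutations <- g$mutations + 1L
  id
}

#' Add a directed typed edge between two existing nodes
#'
#' Both endpoints must already exist (referential integrity). Parallel edges
#' of different types between the same endpoints are allowed; self-edges are
#' permitted but reported by [pg_validate()].
#'
#' @param g A `property_graph`.
#' @param source,target Node ids.
#' @param type Edge type (single string, e.g. `"BELONGS_TO"`).
#' @param attrs Named list of edge attributes (e.g. `confidence`).
#' @return The new edge id (integer), invisibly.
#' @export
pg_add_edge <- function(g, source, target, type, attrs = list()) {
  source <- as.integer(source); target <- as.integer(target)
  if (!pg_has_node(g, source))
    stop("unknown source node: ", source)
  if (!pg_has_node(g, target))
    stop("unknown target node: ", target)
  if (!is.character(type) || length(type) != 1L || !nzchar(type))
    stop("edge type must be a single non-empty string")
  id <- g$next_edge
  g$next_edge <- id + 1L
  assign(as.character(id),
         list(id = id, source = source, target = target, type = type,
              attrs = attrs),
         envir = g$edges)
  ks <- as.character(source); kt <- as.character(target)
  cur <- if (exists(ks, envir = g$out, inherits = FALSE))
    get(ks, envir = g$out) else integer()
  assign(ks, c(cur, id), envir = g$out)
  cur <- if (exists(kt, envir = g$inc, inherits = FALSE))
    get(kt, envir = g$inc) else integer()
  assign(kt, c(cur, id), envir = g$inc)
  g$mutations <- g$mutations + 1L
  invisible(id)
}

#' @rdname pg_node
#' @export
pg_has_node <- function(g, id) {
  exists(as.character(as.integer(id)), envir = g$nodes, inherits = FALSE)
}

#' Retrieve a node, its labels or an attribute
#'
#' @param g A `property_graph`.
#' @param id Node id.
#' @param attr Attribute name.
#' @return `pg_node()`: list with `id`, `labels`, `attrs`; `pg_labels()`:
#'   character vector; `pg_attr()`: the attribute value or `NULL`.
#' @export
pg_node <- function(g, id) {
  k <- as.character(as.integer(id))
  if (!exists(k, envir = g$nodes, inherits = FALSE))
    stop("unknown node: ", id)
  get(k, envir = g$nodes)
}

#' @rdname pg_node
#' @export
pg_labels <- function(g, id) pg_node(g, id)$labels

#' @rdname pg_node
#' @export
pg_attr <- function(g, id, attr) pg_node(g, id)$attrs[[attr]]

#' Set or extend node attributes in place
#' @inheritParams pg_node
#' @param attrs Named list; existing keys are overwritten.
#' @return The node id, invisibly.
#' @export
pg_set_attrs <- function(g, id, attrs) {
  n <- pg_node(g, id)
  n$attrs[names(attrs)] <- attrs
  assign(as.character(n$id), n, envir = g$nodes)
  g$mutations <- g$mutations + 1L
  invisible(n$id)
}

#' Add a label to an existing node
#' @inheritParams pg_node
#' @param label Label to add.
#' @return The node id, invisibly.
#' @export
pg_add_label <- function(g, id, label) {
  n <- pg_node(g, id)
  if (!(label %in% n$labels)) {
    n$labels <- c(n$labels, label)
    assign(as.character(n$id), n, envir = g$nodes)
    cur <- if (exists(label, envir = g$label_index, inherits = FALSE))
      get(label, envir = g$label_index) else integer()
    assign(label, c(cur, n$id), envir = g$label_index)
    g$mutations <- g$mutations + 1L
  }
  invisible(n$id)
}

#' Exact label-index lookup
#'
#' Returns all nodes carrying a label via the label index (no scan). An
#' unknown label yields an empty set.
#'
#' @param g A `property_graph`.
#' @param label Label text.
#' @return Sorted integer vector of node ids.
#' @export
pg_nodes_by_label <- function(g, label) {
  if (exists(label, envir = g$label_index, inherits = FALSE))
    sort(get(label, envir = g$label_index))
  else integer()
}

#' All edges of a store as a data frame
#' @param g A `property_graph`.
#' @return Data frame with columns `id`, `source`, `target`, `type`.
#' @export
pg_edge_table <- function(g) {
  ids <- seq_len(pg_edge_count(g))
  es <- lapply(as.character(ids), function(k) get(k, envir = g$edges))
  data.frame(id = ids,
             source = vapply(es, `[[`, integer(1), "source"),
             target = vapply(es, `[[`, integer(1), "target"),
             type = vapply(es, `[[`, character(1), "type"),
             stringsAsFactors = FALSE)
}

#' @rdname pg_node
#' @export
pg_edge <- function(g, id) get(as.character(as.integer(id)), envir = g$edges)

edge_ids_of <- function(g, id, direction) {
  k <- as.character(as.integer(id))
  out <- if (direction %in% c("out", "both") &&
             exists(k, envir = g$out, inherits = FALSE))
    get(k, envir = g$out) else integer()
  inc <- if (direction %in% c("in", "both") &&
             exists(k, envir = g$inc, inherits = FALSE))
    get(k, envir = g$inc) else integer()
  c(out, inc)
}

#' Edges incident to a node
#'
#' @inheritParams pg_neighbors
#' @return List of edge records (`source`, `target`, `type`, `attrs`).
#' @export
pg_incident_edges <- function(g, id, type = NULL, direction = "both") {
  if (!pg_has_node(g, id)) stop("unknown node: ", id)
  eids <- unique(edge_ids_of(g, id, direction))
  es <- lapply(as.character(eids), function(k) get(k, envir = g$edges))
  if (!is.null(type)) es <- Filter(function(e) e$type == type, es)
  es
}

#' One-hop adjacent nodes
#'
#' Exactly the nodes reachable from `id` by a single edge of the given type
#' and direction; `type = NULL` is the wildcard.
#'
#' @param g A `property_graph`.
#' @param id Node id (must exist).
#' @param type Edge type, or `NULL` for any type.
#' @param direction One of `"out"`, `"in"`, `"both"`.
#' @return Sorted integer vector of distinct neighbor ids.
#' @export
pg_neighbors <- function(g, id, type = NULL, direction = "both") {
  direction <- match.arg(direction, c("out", "in", "both"))
  if (!pg_has_node(g, id)) stop("unknown node: ", id)
  id <- as.integer(id)
  res <- integer()
  for (e in pg_incident_edges(g, id, type, direction)) {
    if (direction %in% c("out", "both") && e$source == id)
      res <- c(res, e$target)
    if (direction %in% c("in", "both") && e$target == id)
      res <- c(res, e$source)
  }
  sort(unique(res))
}

#' Variable-length traversal along one edge type
#'
#' Breadth-first expansion from a start set along edges of a single type,
#' collecting every node whose minimal hop distance lies in
#' `[min_hops, max_hops]`. Cycle-safe via a visited set; `max_hops = Inf`
#' expresses the unbounded `*` pattern.
#'
#' @param g A `property_graph`.
#' @param start Integer vector of start node ids.
#' @param type Edge type, or `NULL` for any.
#' @param direction `"out"`, `"in"` or `"both"`.
#' @param min_hops,max_hops Hop bounds, `0 <= min_hops <= max_hops`.
#' @return Sorted integer vector of node ids.
#' @export
pg_traverse <- function(g, start, type = NULL, direction = "out",
                        min_hops = 1L, max_hops = min_hops) {
  direction <- match.arg(direction, c("out", "in", "both"))
  if (min_hops < 0 || min_hops > max_hops)
    stop("need 0 <= min_hops <= max_hops")
  start <- unique(as.integer(start))
  for (s in start) if (!pg_has_node(g, s)) stop("unknown node: ", s)
  visited <- start
  frontier <- start
  hits <- if (min_hops == 0) start else integer()
  hop <- 0
  while (length(frontier) > 0 && hop < max_hops) {
    hop <- hop + 1
    nxt <- integer()
    for (v in frontier)
      nxt <- c(nxt, pg_neighbors(g, v, type, direction))
    frontier <- setdiff(unique(nxt), visited)
    visited <- c(visited, frontier)
    if (hop >= min_hops) hits <- c(hits, frontier)
  }
  sort(unique(hits))
}

#' Structural validation of a store
#'
#' Checks referential integrity (every edge's endpoints exist), flags
#' self-edges, and verifies upward reachability: every node that is neither
#' a `DOCUMENT` root nor an ontology node must reach exactly one `DOCUMENT`
#' node via `BELONGS_TO` edges.
#'
#' @param g A `property_graph`.
#' @return List with `ok` (logical), `self_edges` (edge ids) and
#'   `unreachable` (node ids without a unique document root).
#' @export
pg_validate <- function(g) {
  self_edges <- integer()
  for (k in as.character(seq_len(pg_edge_count(g)))) {
    e <- get(k, envir = g$edges)
    if (!pg_has_node(g, e$source) || !pg_has_node(g, e$target))
      stop("referential integrity violated at edge ", e$id)
    if (e$source == e$target) self_edges <- c(self_edges, e$id)
  }
  docs <- pg_nodes_by_label(g, "DOCUMENT")
  exempt <- c("DOCUMENT", "ONTOLOGY_ROOT", "ONTOLOGY_CONCEPT", "RESOURCE")
  unreachable <- integer()
  for (id in seq_len(pg_node_count(g))) {
    labs <- pg_labels(g, id)
    if (any(labs %in% exempt)) next
    up <- pg_traverse(g, id, "BELONGS_TO", "out", 1L, Inf)
    if (sum(up %in% docs) != 1L) unreachable <- c(unreachable, id)
  }
  list(ok = length(unreachable) == 0L,
       self_edges = self_edges, unreachable = unreachable)
}

#' Save / load a property graph
#'
#' A versioned plain-text (JSON) serialization: header, nodes section,
#' edges section. Indices are rebuilt on load, so node and edge ids are
#' preserved exactly.
#'
#' @param g A `property_graph`.
#' @param path File path.
#' @return `pg_save()`: the path, invisibly. `pg_load()`: a
#'   `property_graph`.
#' @export
pg_save <- function(g, path) {
  nodes <- lapply(seq_len(pg_node_count(g)), function(id) {
    n <- pg_node(g, id)
    list(id = n$id, labels = as.list(n$labels), attrs = n$attrs)
  })
  edges <- lapply(seq_len(pg_edge_count(g)), function(id) {
    e <- pg_edge(g, id)
    list(source = e$source, target = e$target, type = e$type,
         attrs = e$attrs)
  })
  obj <- list(format = "modelgraph-store", version = 1L,
              nodes = nodes, edges = edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pg_save
#' @export
pg_load <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$format) || obj$format != "modelgraph-store")
    stop("not a modelgraph store file: ", path)
  g <- pg_new()
  for (n in obj$nodes) {
    id <- pg_add_node(g, unlist(n$labels), n$attrs)
    stopifnot(id == n$id)
  }
  for (e in obj$edges)
    pg_add_edge(g, e$source, e$target, e$type, e$attrs)
  rebuild_derived_indices(g)
  g
}

# the resource-deduplication map, ontology registry and concept index are
# derived data; recreate them from node attributes after a load
rebuild_derived_indices <- function(g) {
  for (r in pg_nodes_by_label(g, "RESOURCE")) {
    key <- pg_attr(g, r, "KEY")
    if (!is.null(key)) assign(key, r, envir = resource_index(g))
  }
  for (root in pg_nodes_by_label(g, "ONTOLOGY_ROOT")) {
    tag <- pg_attr(g, root, "TAG")
    if (!is.null(tag)) assign(tag, root, envir = ontology_registry(g))
  }
  for (cn in pg_nodes_by_label(g, "ONTOLOGY_CONCEPT")) {
    cid <- pg_attr(g, cn, "id")
    if (!is.null(cid))
      for (form in concept_id_forms(cid))
        assign(form, cn, envir = concept_index(g))
  }
  invisible(g)
}
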