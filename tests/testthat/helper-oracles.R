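# Independent oracles the implementation is checked against. These work on
# plain edge data frames, never through the package's traversal code.

# random labelled property graph; returns the store plus a plain edge table
# for oracle computations
random_graph <- function(n = 20, p = 0.1, labels = c("A", "B", "C"),
                         types = c("t1", "t2"), seed = 1) {
  set.seed(seed)
  g <- pg_new()
  node_labels <- sample(labels, n, replace = TRUE)
  for (i in seq_len(n))
    pg_add_node(g, node_labels[i], list(NAME = paste0("n", i)))
  edges <- data.frame(source = integer(), target = integer(),
                      type = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && stats::runif(1) < p) {
      ty <- sample(types, 1)
      pg_add_edge(g, i, j, ty)
      edges <- rbind(edges, data.frame(source = i, target = j, type = ty,
                                       stringsAsFactors = FALSE))
    }
  }
  list(g = g, edges = edges, labels = node_labels)
}

# one-hop adjacency by full edge enumeration
oracle_neighbors <- function(edges, id, type = NULL, direction = "both") {
  e <- edges
  if (!is.null(type)) e <- e[e$type == type, , drop = FALSE]
  res <- integer()
  if (direction %in% c("out", "both"))
    res <- c(res, e$target[e$source == id])
  if (direction %in% c("in", "both"))
    res <- c(res, e$source[e$target == id])
  sort(unique(res))
}

# breadth-first minimal hop distances from a start set
oracle_bfs <- function(edges, start, type = NULL, direction = "out",
                       min_hops, max_hops) {
  dist <- stats::setNames(rep(Inf, 0), character())
  frontier <- unique(start)
  for (s in frontier) dist[as.character(s)] <- 0
  d <- 0
  while (length(frontier) && d < max_hops) {
    d <- d + 1
    nxt <- integer()
    for (v in frontier)
      nxt <- c(nxt, oracle_neighbors(edges, v, type, direction))
    nxt <- unique(nxt)
    nxt <- nxt[!(as.character(nxt) %in% names(dist))]
    for (v in nxt) dist[as.character(v)] <- d
    frontier <- nxt
  }
  hit <- names(dist)[dist >= min_hops & dist <= max_hops]
  sort(as.integer(hit))
}

# exhaustive pattern matcher over node tuples (1-hop steps only)
oracle_match <- function(n_nodes, node_labels, edges, pattern) {
  passes <- function(id, st) {
    is.null(st$label) || node_labels[id] == st$label
  }
  adjacent <- function(a, b, st) {
    e <- edges
    if (!is.null(st$edge_type)) e <- e[e$type == st$edge_type, , drop = FALSE]
    ok_out <- any(e$source == a & e$target == b)
    ok_in <- any(e$source == b & e$target == a)
    switch(st$direction, out = ok_out, "in" = ok_in, both = ok_out || ok_in)
  }
  pos_steps <- Filter(function(s) !s$negated, pattern)
  k <- length(pos_steps)
  rows <- list()
  recurse <- function(tuple, step_idx) {
    if (step_idx > length(pattern)) {
      rows[[length(rows) + 1L]] <<- tuple
      return(invisible())
    }
    st <- pattern[[step_idx]]
    anchor <- tuple[length(tuple)]
    if (st$negated) {
      cand <- Filter(function(c_) c_ != anchor && !(c_ %in% tuple) &&
                       passes(c_, st) && adjacent(anchor, c_, st),
                     seq_len(n_nodes))
      if (!length(cand)) recurse(tuple, step_idx + 1L)
      return(invisible())
    }
    for (c_ in seq_len(n_nodes)) {
      if (c_ %in% tuple) next
      if (!passes(c_, st)) next
      if (!adjacent(anchor, c_, st)) next
      recurse(c(tuple, c_), step_idx + 1L)
    }
  }
  s1 <- pattern[[1]]
  for (start in seq_len(n_nodes))
    if (passes(start, s1)) recurse(start, 2L)
  if (!length(rows))
    return(matrix(integer(), ncol = k, nrow = 0))
  m <- do.call(rbind, rows)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# random single-hop pattern (2-3 steps, optionally ending negated)
random_pattern <- function(labels, types) {
  k <- sample(2:3, 1)
  steps <- list(p_step(label = sample(c(labels, list(NULL)), 1)[[1]]))
  for (i in 2:k) {
    steps[[i]] <- p_step(
      label = sample(c(labels, list(NULL)), 1)[[1]],
      edge_type = sample(c(types, list(NULL)), 1)[[1]],
      direction = sample(c("out", "in", "both"), 1),
      negated = (i == k && stats::runif(1) < 0.25))
  }
  steps
}

# transitive descendants by depth-first search over parent lists
oracle_descendants <- function(parents, concept) {
  out <- character()
  stack <- concept
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    if (cur %in% out) next
    out <- c(out, cur)
    kids <- names(parents)[vapply(parents, function(p) cur %in% p,
                                  logical(1))]
    stack <- c(stack, kids)
  }
  sort(out)
}

# quadratic all-pairs suffix comparison for link type (a)
oracle_suffix_links <- function(uris, concept_ids, tag, k = 7) {
  suffix <- function(x) substring(x, pmax(1, nchar(x) - k + 1))
  hits <- 0L
  for (u in uris) {
    if (!grepl(tag, toupper(u), fixed = TRUE)) next
    hits <- hits + sum(suffix(concept_ids) == suffix(u))
  }
  hits
}

# streaming recomputation of grouped statistics
oracle_stats <- function(v) {
  n <- length(v); m <- sum(v) / n
  list(min = min(v), max = max(v), avg = m,
       stdev = if (n > 1) sqrt(sum((v - m)^2) / (n - 1)) else NA_real_)
}
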