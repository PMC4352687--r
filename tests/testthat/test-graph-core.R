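test_that("node insertion updates the label index and enforces contracts", {
  g <- pg_new()
  id <- pg_add_node(g, "SBML_SPECIES", list(ID = "pM"))
  expect_true(id %in% pg_nodes_by_label(g, "SBML_SPECIES"))
  expect_equal(pg_attr(g, id, "ID"), "pM")

  r <- pg_add_node(g, "RESOURCE",
                   list(URI = "urn:miriam:obo.go:GO%3A0005892"))
  expect_true(r %in% pg_nodes_by_label(g, "RESOURCE"))

  expect_error(pg_add_node(g, character()), "label")
  expect_error(pg_add_node(g, "X", list(1, 2)), "named")

  # distinct labels resolve to exactly one node each
  g2 <- pg_new()
  ids <- vapply(1:100, function(i) pg_add_node(g2, paste0("L", i)),
                integer(1))
  expect_equal(length(unique(ids)), 100L)
  for (i in 1:100)
    expect_equal(pg_nodes_by_label(g2, paste0("L", i)), ids[i])
  expect_equal(pg_nodes_by_label(g2, "no-such-label"), integer())
})

test_that("edges require existing endpoints; self-edges are flagged", {
  g <- pg_new()
  cell <- pg_add_node(g, "SBML_COMPARTMENT", list(ID = "Cell"))
  pm <- pg_add_node(g, "SBML_SPECIES", list(ID = "pM"))
  pg_add_edge(g, pm, cell, "isContainedIn")
  expect_equal(pg_neighbors(g, cell, "isContainedIn", "in"), pm)
  expect_error(pg_add_edge(g, pm, 99L, "x"), "unknown target")
  expect_error(pg_add_edge(g, 99L, pm, "x"), "unknown source")

  n <- pg_add_node(g, "C")
  pg_add_edge(g, n, n, "isA")
  v <- pg_validate(g)
  expect_length(v$self_edges, 1L)
})

test_that("label index equals a brute-force scan of node labels", {
  rg <- random_graph(n = 40, p = 0.08, seed = 42)
  for (lab in c("A", "B", "C"))
    expect_equal(pg_nodes_by_label(rg$g, lab), which(rg$labels == lab))
})

test_that("neighbors matches a full edge-scan oracle on random graphs", {
  for (seed in 1:10) {
    rg <- random_graph(n = 30, p = 0.1, seed = seed)
    for (id in sample(30, 8)) {
      for (dir in c("out", "in", "both")) {
        expect_equal(pg_neighbors(rg$g, id, NULL, dir),
                     oracle_neighbors(rg$edges, id, NULL, dir),
                     info = sprintf("seed %d node %d dir %s", seed, id, dir))
        expect_equal(pg_neighbors(rg$g, id, "t1", dir),
                     oracle_neighbors(rg$edges, id, "t1", dir))
      }
    }
    isolated <- setdiff(seq_len(30), unique(c(rg$edges$source,
                                              rg$edges$target)))
    if (length(isolated))
      expect_equal(pg_neighbors(rg$g, isolated[1], NULL, "both"), integer())
  }
  expect_error(pg_neighbors(pg_new(), 1L), "unknown node")
})

test_that("traverse equals an independent BFS oracle (100 seeded trials)", {
  for (seed in 1:100) {
    rg <- random_graph(n = sample(5:50, 1), p = 0.08,
                       seed = seed + 1000)
    n <- pg_node_count(rg$g)
    start <- sample(n, min(2, n))
    bounds <- list(c(0, 0), c(1, 1), c(1, 2), c(0, Inf), c(2, Inf))
    b <- bounds[[(seed %% length(bounds)) + 1]]
    dir <- c("out", "in", "both")[(seed %% 3) + 1]
    expect_equal(
      pg_traverse(rg$g, start, NULL, dir, b[1], b[2]),
      oracle_bfs(rg$edges, start, NULL, dir, b[1], b[2]),
      info = sprintf("seed %d", seed))
  }
})

test_that("traverse handles identity and invalid bounds", {
  g <- pg_new()
  a <- pg_add_node(g, "A"); b <- pg_add_node(g, "B")
  pg_add_edge(g, a, b, "t")
  expect_equal(pg_traverse(g, a, "t", "out", 0, 0), a)
  expect_error(pg_traverse(g, a, "t", "out", 3, 1), "min_hops")
  # cycle safety: minimal hop distances, the start stays at depth 0
  pg_add_edge(g, b, a, "t")
  expect_equal(pg_traverse(g, a, "t", "out", 1, Inf), b)
  expect_equal(pg_traverse(g, a, "t", "out", 0, Inf), sort(c(a, b)))
})

test_that("save/load round-trips nodes, edges, attributes and indices", {
  rg <- random_graph(n = 25, p = 0.12, seed = 7)
  g <- rg$g
  pg_set_attrs(g, 1L, list(SCORE = 0.5, FLAG = TRUE))
  path <- tempfile(fileext = ".json")
  pg_save(g, path)
  g2 <- pg_load(path)
  expect_equal(pg_node_count(g2), pg_node_count(g))
  expect_equal(pg_edge_count(g2), pg_edge_count(g))
  expect_equal(pg_edge_table(g2), pg_edge_table(g))
  for (lab in c("A", "B", "C"))
    expect_equal(pg_nodes_by_label(g2, lab), pg_nodes_by_label(g, lab))
  expect_equal(pg_attr(g2, 1L, "SCORE"), 0.5)
  suppressWarnings(
    expect_error(pg_load(tempfile()),
                 "cannot open|No such|not a modelgraph"))
})

test_that("imported stores satisfy upward document reachability", {
  d <- tempfile()
  files <- write_paper_fixtures(d)
  g <- pg_new()
  import_sbml(g, files[["tyson_sbml"]])
  import_cellml(g, files[["tyson_cellml"]])
  import_sedml(g, files[["sedml"]])
  v <- pg_validate(g)
  expect_true(v$ok)
  expect_length(v$unreachable, 0L)
})
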