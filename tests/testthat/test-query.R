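test_that("pattern matching equals exhaustive enumeration on random graphs", {
  for (trial in 1:50) {
    rg <- random_graph(n = sample(8:40, 1), p = 0.09, seed = trial + 500)
    set.seed(trial)
    pattern <- random_pattern(c("A", "B", "C"), c("t1", "t2"))
    got <- pg_match(rg$g, pattern)
    want <- oracle_match(pg_node_count(rg$g), rg$labels, rg$edges, pattern)
    expect_equal(nrow(got), nrow(want), info = paste("trial", trial))
    if (nrow(want))
      expect_equal(unname(as.matrix(got)), unname(want),
                   info = paste("trial", trial))
  }
})

test_that("patterns over an empty store return zero rows", {
  g <- pg_new()
  out <- pg_match(g, list(p_step(label = "SBML_MODEL")))
  expect_equal(nrow(out), 0L)
  expect_error(pg_match(g, list()), "empty")
})

test_that("attribute filters support equals, regex and contains", {
  g <- pg_new()
  a <- pg_add_node(g, "R", list(URI = "urn:miriam:obo.go:GO%3A0005892"))
  b <- pg_add_node(g, "R", list(URI = "urn:miriam:obo.go:GO%3A0007049"))
  eq <- pg_match(g, list(p_step("R", filters = list(
    p_filter("URI", "equals", "urn:miriam:obo.go:GO%3A0007049")))))
  expect_equal(eq$v1, b)
  re <- pg_match(g, list(p_step("R", filters = list(
    p_filter("URI", "regex", ".*GO.*0005892")))))
  expect_equal(re$v1, a)
  ct <- pg_match(g, list(p_step("R", filters = list(
    p_filter("URI", "contains", "obo.go")))))
  expect_equal(ct$v1, c(a, b))
})

test_that("grouped aggregates match hand computation and an oracle", {
  # components of sizes 1, 2, 3
  rows <- data.frame(comp = rep(c("x", "y", "z"), times = 1:3),
                     var = 1:6)
  out <- pg_aggregate(rows, group_by = "comp",
                      aggregates = list(n = list(fun = "count")))
  expect_equal(out$n, c(1L, 2L, 3L))
  stats <- pg_aggregate(out, aggregates = list(
    avg = list(fun = "avg", var = "n"),
    stdev = list(fun = "stdev", var = "n")))
  expect_equal(stats$avg, 2)
  expect_equal(stats$stdev, 1)

  set.seed(17)
  for (i in 1:100) {
    v <- sample(1:50, sample(2:20, 1), replace = TRUE)
    df <- data.frame(x = v)
    got <- pg_aggregate(df, aggregates = list(
      min = list(fun = "min", var = "x"), max = list(fun = "max", var = "x"),
      avg = list(fun = "avg", var = "x"),
      stdev = list(fun = "stdev", var = "x")))
    want <- oracle_stats(v)
    expect_equal(got$min, want$min)
    expect_equal(got$max, want$max)
    expect_equal(got$avg, want$avg)
    expect_equal(got$stdev, want$stdev)
  }
  expect_error(pg_aggregate(rows, aggregates = list(
    n = list(fun = "count", var = "ghost"))), "unbound")
})

test_that("ordering and limits break ties deterministically", {
  rows <- data.frame(NAME = c("beta", "alpha", "gamma"),
                     n = c(5L, 5L, 2L), stringsAsFactors = FALSE)
  top <- pg_aggregate(rows, group_by = "NAME",
                      aggregates = list(cnt = list(fun = "max", var = "n")),
                      order_by = "cnt", descending = TRUE, limit = 1)
  expect_equal(top$NAME, "alpha")
})

test_that("text search returns token-containing resources ranked by TF-IDF", {
  g <- pg_new()
  phrase_uris <- sprintf("urn:miriam:uniprot:P%05d", 1:7)
  for (u in phrase_uris) {
    r <- pg_resource_node(g, u)
    pg_set_attrs(g, r, list(
      RESOURCETEXT = paste("m-phase inducer phosphatase record", u)))
  }
  decoy_uris <- sprintf("urn:miriam:uniprot:Q%05d", 1:20)
  for (u in decoy_uris) {
    r <- pg_resource_node(g, u)
    pg_set_attrs(g, r, list(
      RESOURCETEXT = paste("unrelated oxidoreductase record", u)))
  }
  hits <- text_search(g, "m-phase inducer phosphatase")
  expect_setequal(hits$URI, phrase_uris)
  # substring-scan oracle
  all_res <- pg_nodes_by_label(g, "RESOURCE")
  oracle <- Filter(function(r) {
    txt <- tolower(pg_attr(g, r, "RESOURCETEXT"))
    all(vapply(c("m", "phase", "inducer", "phosphatase"), grepl,
               logical(1), x = txt, fixed = TRUE))
  }, all_res)
  expect_setequal(hits$node, unlist(oracle))
  # absent token: empty result; empty query: error
  expect_equal(nrow(text_search(g, "nonexistenttoken")), 0L)
  expect_error(text_search(g, "  ,, "), "empty")
})

test_that("doubling a term's frequency strictly increases its score", {
  g <- pg_new()
  r1 <- pg_resource_node(g, "urn:miriam:uniprot:A00001")
  r2 <- pg_resource_node(g, "urn:miriam:uniprot:A00002")
  pg_set_attrs(g, r1, list(RESOURCETEXT = "phosphatase enzyme"))
  pg_set_attrs(g, r2, list(RESOURCETEXT = "phosphatase phosphatase enzyme"))
  pg_resource_node(g, "urn:miriam:uniprot:A00003")  # idf background
  hits <- text_search(g, "phosphatase")
  expect_equal(hits$node[1], r2)
  expect_gt(hits$score[1], hits$score[2])
})

test_that("closure-based annotation counts equal direct plus descendants", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: SYN:0000001", "name: parent", "",
               "[Term]", "id: SYN:0000002", "name: child a",
               "is_a: SYN:0000001", "",
               "[Term]", "id: SYN:0000003", "name: child b",
               "is_a: SYN:0000001"), f)
  g <- pg_new()
  import_ontology(g, f, "SYN")
  doc <- pg_add_node(g, "DOCUMENT", list(FILENAME = "x"))
  mk_ann <- function(uri) {
    ann <- pg_add_node(g, "ANNOTATION")
    pg_add_edge(g, ann, doc, "BELONGS_TO")
    res <- pg_resource_node(g, uri)
    pg_add_edge(g, ann, res, "isVersionOf")
    pg_add_edge(g, res, ann, "BELONGS_TO")
  }
  # 3 resources -> parent suffix, 2 -> child a
  for (i in 1:3) mk_ann("urn:miriam:syn:SYN%3A0000001")
  for (i in 1:2) mk_ann("urn:miriam:syn:SYN%3A0000002")
  link_annotations_to_ontology(g, "SYN")
  got <- canned_query(g, "annotation_count_with_descendants",
                      list(concept = "SYN:0000001"))
  expect_equal(got$total, 5L)
  expect_equal(got$direct, 3L)
  # brute force over the closure
  expect_equal(got$total,
               sum(vapply(descendants(g, "SYN:0000001"), function(cid) {
                 cn <- concept_node(g, cid)
                 sum(vapply(pg_neighbors(g, cn, "IS_ONTOLOGY_ENTRY", "in"),
                            function(r) length(pg_incident_edges(g, r, NULL,
                                                                 "in")),
                            integer(1)))
               }, integer(1))))
})

test_that("cross-domain retrieval applies all three filters", {
  ps <- paper_store()
  g <- ps$g
  # full query: phrase + qualifier 'is' + modifier role
  q4 <- canned_query(g, "experiments_observing",
                     list(phrase = "m-phase inducer phosphatase"))
  expect_equal(q4$Species, "CP")
  expect_equal(q4$SEDML, "tyson1991-sedml-synthetic.xml")
  # three-filter brute-force oracle
  oracle_rows <- 0L
  for (s in pg_nodes_by_label(g, "SBML_SPECIES")) {
    anns <- pg_neighbors(g, s, "hasAnnotation", "out")
    has_qual <- any(vapply(anns, function(a)
      any(vapply(pg_incident_edges(g, a, "is", "out"), function(e) {
        txt <- pg_attr(g, e$target, "RESOURCETEXT")
        !is.null(txt) && grepl("phosphatase", tolower(txt))
      }, logical(1))), logical(1)))
    observed <- length(pg_neighbors(g, s, "OBSERVES", "in")) > 0
    modifier <- length(pg_incident_edges(g, s, "IS_MODIFIER", "out")) > 0
    if (has_qual && observed && modifier) oracle_rows <- oracle_rows + 1L
  }
  expect_equal(nrow(q4), oracle_rows)
  # dropping any filter must not shrink the result
  q4_react <- canned_query(g, "experiments_observing",
                           list(phrase = "m-phase inducer phosphatase",
                                role = "IS_REACTANT"))
  expect_equal(nrow(q4_react), 0L)  # CP is never a reactant
})

test_that("statistics queries equal an independent recomputation", {
  ps <- paper_store()
  g <- ps$g
  m5 <- canned_query(g, "variables_per_component_stats")
  counts <- vapply(pg_nodes_by_label(g, "CELLMLCOMPONENT"), function(c_)
    length(pg_neighbors(g, c_, "hasVariable", "out")), integer(1))
  want <- oracle_stats(counts)
  expect_equal(m5$min, want$min)
  expect_equal(m5$max, want$max)
  expect_equal(m5$avg, want$avg)
  expect_equal(m5$stdev, want$stdev)

  q7 <- canned_query(g, "annotation_stats_per_model")
  per_model <- integer()
  for (m in pg_nodes_by_label(g, "SBML_MODEL")) {
    anns <- intersect(pg_traverse(g, m, "BELONGS_TO", "in", 1, 2),
                      pg_nodes_by_label(g, "ANNOTATION"))
    n <- sum(vapply(anns, function(a)
      length(Filter(function(e) "RESOURCE" %in% pg_labels(g, e$source),
                    pg_incident_edges(g, a, "BELONGS_TO", "in"))),
      integer(1)))
    if (n > 0) per_model <- c(per_model, n)
  }
  want <- oracle_stats(per_model)
  expect_equal(q7$avg, want$avg)
  expect_equal(q7$stdev, want$stdev)
  expect_equal(q7$max, want$max)
})

test_that("unknown canned queries list the valid names", {
  expect_error(canned_query(pg_new(), "nope"), "valid names")
})

test_that("identical stores yield identical serialized query results", {
  build <- function() {
    ps <- paper_store()
    ps$g
  }
  g1 <- build(); g2 <- build()
  for (q in list(list("list_species", list(model = "BIOMD0000000001")),
                 list("top_annotations", list(n = 5)),
                 list("elements_annotated_with",
                      list(regex = ".*GO.*0005892")))) {
    r1 <- capture.output(print(canned_query(g1, q[[1]], q[[2]])))
    r2 <- capture.output(print(canned_query(g2, q[[1]], q[[2]])))
    expect_identical(r1, r2)
  }
})
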