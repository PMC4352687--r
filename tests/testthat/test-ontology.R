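binary_tree_obo <- function(path, depth = 3) {
  terms <- list(); idx <- 0L
  build <- function(parent, level) {
    idx <<- idx + 1L
    id <- sprintf("BT:%07d", idx)
    terms[[length(terms) + 1L]] <<- list(
      id = id, name = paste0("node", idx), def = "binary tree node",
      parents = if (is.null(parent)) character() else parent)
    if (level < depth) { build(id, level + 1L); build(id, level + 1L) }
    id
  }
  build(NULL, 1L)
  emit_obo_file(path, terms)
  terms
}

# tests build OBO files through a tiny local writer so the parser under
# test is not checked against the package's own emitter alone
emit_obo_file <- function(path, terms) {
  ln <- c("format-version: 1.2", "")
  for (t in terms) {
    ln <- c(ln, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.null(t$def)) ln <- c(ln, paste0("def: \"", t$def, "\" [src]"))
    for (p in t$parents) ln <- c(ln, paste0("is_a: ", p, " ! comment"))
    ln <- c(ln, "")
  }
  writeLines(ln, path)
}

test_that("a small constructed ontology maps to concepts and isA edges", {
  f <- tempfile(fileext = ".obo")
  emit_obo_file(f, list(
    list(id = "SBO:0000009", name = "kinetic constant",
         def = "velocity quantifier", parents = character()),
    list(id = "SBO:0000027", name = "Michaelis constant",
         parents = "SBO:0000009"),
    list(id = "SBO:0000332", name = "half-life", parents = "SBO:0000009"),
    list(id = "SBO:0000036", name = "bimolecular rate constant",
         parents = "SBO:0000009")))
  g <- pg_new()
  counts <- import_ontology(g, f, "SBO")
  expect_equal(unname(counts["concepts"]), 4)
  expect_equal(unname(counts["isa_edges"]), 3)
  # resolvable by id in both spellings
  n1 <- concept_node(g, "SBO:0000009")
  n2 <- concept_node(g, "SBO_0000009")
  expect_equal(n1, n2)
  expect_equal(pg_attr(g, n1, "NAME"), "kinetic constant")
  expect_setequal(descendants(g, "SBO:0000009"),
                  c("SBO:0000009", "SBO:0000027", "SBO:0000332",
                    "SBO:0000036"))
  expect_equal(descendants(g, "SBO:0000027"), "SBO:0000027")
  expect_error(descendants(g, "SBO:9999999"), "unknown")
  # tag collision is rejected
  expect_error(import_ontology(g, f, "SBO"), "already imported")
})

test_that("a 3-level complete binary tree closes to 7 concepts", {
  f <- tempfile(fileext = ".obo")
  binary_tree_obo(f, depth = 3)
  g <- pg_new()
  counts <- import_ontology(g, f, "BT")
  expect_equal(unname(counts["concepts"]), 7)
  expect_length(descendants(g, "BT:0000001"), 7L)
})

test_that("descendants equals a DFS oracle on a 200-node random DAG", {
  set.seed(99)
  n <- 200
  ids <- sprintf("DAG:%07d", seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1) return(character())
    k <- sample(0:2, 1, prob = c(0.2, 0.6, 0.2))
    if (k == 0) character() else ids[sample(seq_len(i - 1), min(k, i - 1))]
  })
  names(parents) <- ids
  f <- tempfile(fileext = ".obo")
  emit_obo_file(f, lapply(seq_len(n), function(i) list(
    id = ids[i], name = paste0("c", i), parents = parents[[i]])))
  g <- pg_new()
  import_ontology(g, f, "DAG")
  for (cid in ids)
    expect_equal(descendants(g, cid), oracle_descendants(parents, cid),
                 info = cid)
})

test_that("cyclic isA graphs are rejected with the cycle named", {
  f <- tempfile(fileext = ".obo")
  emit_obo_file(f, list(
    list(id = "X:0000001", name = "a", parents = "X:0000002"),
    list(id = "X:0000002", name = "b", parents = "X:0000001")))
  expect_error(import_ontology(pg_new(), f, "X"), "cyclic isA")
})

test_that("the OWL-XML subset imports classes, labels and subClassOf", {
  f <- tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:owl=\"http://www.w3.org/2002/07/owl#\">",
    "  <owl:Class rdf:about=\"http://example.org/KISAO_0000000\">",
    "    <rdfs:label>simulation algorithm</rdfs:label>",
    "  </owl:Class>",
    "  <owl:Class rdf:about=\"http://example.org/KISAO_0000019\">",
    "    <rdfs:label>CVODE</rdfs:label>",
    "    <rdfs:subClassOf rdf:resource=\"http://example.org/KISAO_0000000\"/>",
    "  </owl:Class>",
    "</rdf:RDF>"), f)
  g <- pg_new()
  counts <- import_ontology(g, f, "KISAO")
  expect_equal(unname(counts["concepts"]), 2)
  expect_equal(unname(counts["isa_edges"]), 1)
  expect_setequal(descendants(g, "KISAO_0000000"),
                  c("KISAO_0000000", "KISAO_0000019"))
})
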