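corpus_hash <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  vapply(files, function(f) unname(tools::md5sum(f)), character(1))
}

test_that("identical specs produce byte-identical corpora", {
  spec <- synthetic_spec(seed = 4, n_models = 3)
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  generate_corpus(spec, d1)
  generate_corpus(spec, d2)
  expect_equal(unname(corpus_hash(d1)), unname(corpus_hash(d2)))
  d3 <- tempfile("c3")
  generate_corpus(synthetic_spec(seed = 5, n_models = 3), d3)
  expect_false(identical(unname(corpus_hash(d1)),
                         unname(corpus_hash(d3))))
})

test_that("emitted files pass the importers' well-formedness checks", {
  out <- generate_corpus(synthetic_spec(seed = 6, n_models = 3,
                                        twin_fraction = 1),
                         tempfile("corpus"))
  g <- pg_new()
  for (nm in names(out$files)) {
    f <- out$files[[nm]]
    if (grepl("^sbml", nm)) expect_no_error(import_sbml(g, f))
    else if (grepl("^cellml", nm)) expect_no_error(import_cellml(g, f))
    else if (grepl("^sedml", nm)) expect_no_error(import_sedml(g, f))
    else if (nm == "ontology")
      expect_no_error(import_ontology(g, f, "SYN"))
  }
  v <- pg_validate(g)
  expect_true(v$ok)
})

test_that("planted annotations correspond to content in the files", {
  out <- generate_corpus(synthetic_spec(seed = 9, n_models = 5,
                                        annotation_density = 1,
                                        twin_fraction = 0),
                         tempfile("corpus"))
  g <- pg_new()
  import_ontology(g, out$files[["ontology"]], "SYN")
  for (f in grep("^sbml", names(out$files), value = TRUE))
    import_sbml(g, out$files[[f]])
  created <- link_annotations_to_ontology(g, "SYN")
  n_planted <- sum(vapply(out$truth$documents, function(d)
    length(d$annotations), integer(1)))
  expect_gt(n_planted, 0)
  # every planted (element, concept) pair is linked in the store
  for (doc in out$truth$documents) {
    for (pa in doc$annotations) {
      sp <- Filter(function(n) identical(pg_attr(g, n, "ID"), pa$element),
                   pg_nodes_by_label(g, "SBML_SPECIES"))
      expect_length(sp, 1L)
      res <- unlist(lapply(pg_neighbors(g, sp[[1]], "hasAnnotation", "out"),
                           function(a) pg_neighbors(g, a, "isVersionOf",
                                                    "out")))
      concepts <- unlist(lapply(res, function(r)
        pg_neighbors(g, r, "IS_ONTOLOGY_ENTRY", "out")))
      expect_true(pa$concept %in%
                    vapply(concepts, function(c_) pg_attr(g, c_, "id"),
                           character(1)))
    }
  }
})

test_that("zero annotation density leaves only publication resources", {
  out <- generate_corpus(synthetic_spec(seed = 10, n_models = 3,
                                        annotation_density = 0,
                                        twin_fraction = 0),
                         tempfile("corpus"))
  g <- pg_new()
  for (f in grep("^sbml", names(out$files), value = TRUE))
    import_sbml(g, out$files[[f]])
  res <- pg_nodes_by_label(g, "RESOURCE")
  expect_true(all(vapply(res, function(r)
    "PUBLICATION" %in% pg_labels(g, r), logical(1))))
})

test_that("zero twin fraction yields no cross-format links at any threshold", {
  out <- generate_corpus(synthetic_spec(seed = 12, n_models = 3,
                                        twin_fraction = 0),
                         tempfile("corpus"))
  g <- pg_new()
  for (f in grep("^sbml", names(out$files), value = TRUE))
    import_sbml(g, out$files[[f]])
  expect_equal(nrow(infer_cross_format_links(g, threshold = 0)), 0L)
})

test_that("the bundled worked-example fixtures reproduce their documentation", {
  d <- tempfile()
  files <- write_paper_fixtures(d)
  g <- pg_new()
  import_sbml(g, files[["edelstein1"]])
  got <- canned_query(g, "elements_annotated_with",
                      list(regex = ".*GO.*0005892"))
  expect_length(unique(got$ElementID), 12L)
  expect_equal(unique(got$Qualifier), "isVersionOf")
  import_cellml(g, files[["tyson_cellml"]])
  comps <- canned_query(g, "list_components", list(name = "tyson_1991"))
  expect_setequal(comps$Component,
                  c("YP", "Y", "M", "pM", "CP", "C2", "environment",
                    "reaction_constants"))
  import_sbml(g, files[["tyson_sbml"]])
  import_sedml(g, files[["sedml"]])
  link_sedml_to_models(g)
  sims <- canned_query(g, "simulations_for_model",
                       list(name = "Tyson1991 - Cell Cycle"))
  expect_equal(sims$SEDMLFile, "tyson1991-sedml-synthetic.xml")
})
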