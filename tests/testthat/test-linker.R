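test_that("suffix matching equals the quadratic oracle on planted fixtures", {
  set.seed(3)
  f <- tempfile(fileext = ".obo")
  concept_ids <- sprintf("SYN:%07d", 1:30)
  writeLines(c("format-version: 1.2", "",
               unlist(lapply(concept_ids, function(id) c(
                 "[Term]", paste0("id: ", id),
                 paste0("name: concept ", id), "")))), f)
  g <- pg_new()
  import_ontology(g, f, "SYN")
  # 20 planted matches, 30 decoys (bad suffix or missing tag)
  planted <- sprintf("urn:miriam:syn:SYN%%3A%07d", 1:20)
  decoys <- c(sprintf("urn:miriam:syn:SYN%%3A%07d", 9000001:9000015),
              sprintf("urn:miriam:other:OTR%%3A%07d", 1:15))
  uris <- sample(c(planted, decoys))
  for (u in uris) pg_resource_node(g, u)
  created <- link_annotations_to_ontology(g, "SYN")
  expect_equal(created, 20L)
  expect_equal(created,
               oracle_suffix_links(uris, concept_ids, "SYN"))
  # second run is a no-op
  expect_equal(link_annotations_to_ontology(g, "SYN"), 0L)
  # resource text was extended with the concept label
  res <- pg_nodes_by_label(g, "RESOURCE")
  linked <- Filter(function(r)
    length(pg_neighbors(g, r, "IS_ONTOLOGY_ENTRY", "out")) > 0, res)
  expect_match(pg_attr(g, linked[[1]], "RESOURCETEXT"), "concept")
})

test_that("a store without matching resources yields zero links", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: SBO:0000009",
               "name: kinetic constant"), f)
  g <- pg_new()
  import_ontology(g, f, "SBO")
  expect_equal(link_annotations_to_ontology(g, "SBO"), 0L)
  expect_error(link_annotations_to_ontology(g, "GO"), "no imported ontology")
})

test_that("a resource matching two concepts is an error, not a pick", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: SBO:0000009", "name: a", "",
               "[Term]", "id: XBO:0000009", "name: b"), f)
  g <- pg_new()
  import_ontology(g, f, "SBO")
  pg_resource_node(g, "urn:miriam:biomodels.sbo:SBO%3A0000009")
  expect_error(link_annotations_to_ontology(g, "SBO"),
               "multiple concepts")
})

test_that("SED-ML model references resolve against stored models", {
  out <- generate_corpus(synthetic_spec(seed = 21, n_models = 10,
                                        twin_fraction = 0),
                         tempfile("corpus"))
  g <- pg_new()
  for (f in grep("^sbml", names(out$files), value = TRUE))
    import_sbml(g, out$files[[f]])
  for (f in grep("^sedml", names(out$files), value = TRUE))
    import_sedml(g, out$files[[f]])
  res <- link_sedml_to_models(g)
  expect_equal(nrow(res$links), 10L)
  expect_length(res$unresolved, 0L)
  expect_true(all(res$links$confidence == 1))
  # ground truth: each reference points at its own model document
  for (i in seq_len(nrow(res$links))) {
    ref <- res$links$source[i]; m <- res$links$target[i]
    src <- pg_attr(g, ref, "MODELSOURCE")
    doc <- pg_neighbors(g, m, "BELONGS_TO", "out")
    expect_equal(pg_attr(g, doc, "FILENAME"), src)
  }
  # idempotence
  expect_equal(nrow(link_sedml_to_models(g)$links), 0L)
})

test_that("unresolvable model references are reported, not linked", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    "<sedML xmlns=\"http://sed-ml.org/\" level=\"1\" version=\"1\">",
    "  <listOfSimulations><uniformTimeCourse id=\"s1\">",
    "    <algorithm kisaoID=\"KISAO:0000019\"/>",
    "  </uniformTimeCourse></listOfSimulations>",
    "  <listOfModels><model id=\"m1\" source=\"absent.xml\"/></listOfModels>",
    "  <listOfTasks><task id=\"t1\" modelReference=\"m1\"",
    "    simulationReference=\"s1\"/></listOfTasks>",
    "</sedML>"), f)
  g <- pg_new()
  import_sedml(g, f)
  res <- link_sedml_to_models(g)
  expect_equal(nrow(res$links), 0L)
  expect_equal(res$unresolved, "absent.xml")
})

test_that("data-generator targets resolve to observed entities", {
  out <- generate_corpus(synthetic_spec(seed = 31, n_models = 6,
                                        twin_fraction = 0),
                         tempfile("corpus"))
  g <- pg_new()
  for (f in grep("^sbml", names(out$files), value = TRUE))
    import_sbml(g, out$files[[f]])
  for (f in grep("^sedml", names(out$files), value = TRUE))
    import_sedml(g, out$files[[f]])
  link_sedml_to_models(g)
  res <- link_datagenerators_to_entities(g)
  n_observed <- sum(vapply(out$truth$sedml, function(s)
    length(s$observed), integer(1)))
  expect_equal(nrow(res$links), n_observed)
  expect_length(res$unresolved, 0L)
  # every OBSERVES edge hits exactly a planted target
  observed_ids <- sort(unname(unlist(lapply(out$truth$sedml, `[[`,
                                            "observed"))))
  got <- sort(vapply(res$links$target, function(e)
    pg_attr(g, e, "ID"), character(1)))
  expect_equal(got, observed_ids)
  # change elements flagged their species
  for (s in out$truth$sedml) {
    sp <- Filter(function(n) identical(pg_attr(g, n, "ID"), s$changed),
                 pg_nodes_by_label(g, "SBML_SPECIES"))
    expect_true(any(vapply(sp, function(n)
      isTRUE(pg_attr(g, n, "IS_CHANGED")), logical(1))))
  }
  # idempotence
  expect_equal(nrow(link_datagenerators_to_entities(g)$links), 0L)
})

test_that("cross-format matcher meets recall targets on planted twins", {
  tw <- generate_twin_pair(tempfile("twin"), seed = 8)
  g <- pg_new()
  import_sbml(g, tw$sbml)
  import_cellml(g, tw$cellml)
  links <- infer_cross_format_links(g, threshold = 0.7)
  expect_gt(nrow(links), 0)
  name_of <- function(n) {
    nm <- pg_attr(g, n, "NAME"); if (is.null(nm)) pg_attr(g, n, "ID") else nm
  }
  linked_pairs <- unique(data.frame(
    s = vapply(links$source, name_of, character(1)),
    c = vapply(links$target, name_of, character(1)),
    stringsAsFactors = FALSE))
  truth <- tw$truth$pairs
  hit <- mapply(function(s, c_) any(linked_pairs$s == s & linked_pairs$c == c_),
                truth$sbml_name, truth$cellml_name)
  # recall 1.0 on exact-name pairs, >= 0.8 overall
  expect_equal(mean(hit[!truth$perturbed]), 1.0)
  expect_gte(mean(hit), 0.8)
  # zero decoy links
  expect_false(any(linked_pairs$s %in% tw$truth$decoys_sbml))
  expect_false(any(linked_pairs$c %in% tw$truth$decoys_cellml))
  # confidences respect the threshold and brute-force rescoring
  expect_true(all(links$confidence >= 0.7))
  # idempotence
  expect_equal(nrow(infer_cross_format_links(g, 0.7)), 0L)
})

test_that("no shared publication means no links, whatever the names", {
  tw <- generate_twin_pair(tempfile("twin"), seed = 8,
                           shared_publication = FALSE)
  g <- pg_new()
  import_sbml(g, tw$sbml)
  import_cellml(g, tw$cellml)
  expect_equal(nrow(infer_cross_format_links(g, threshold = 0)), 0L)
})

test_that("name similarity is symmetric and monotone in edit distance", {
  expect_equal(name_similarity("C2", "C2"), 1)
  expect_equal(name_similarity("Cdc25", "cdc25"), 1)  # case folding
  for (pair in list(c("kinase", "kinases"), c("binding", "bind"))) {
    expect_gt(name_similarity(pair[1], pair[2]), 0.9)  # stemming
  }
  a <- "phosphatase"
  d1 <- name_similarity(a, "phosphatasX")
  d2 <- name_similarity(a, "phosphaXXXX")
  expect_gt(d1, d2)
  expect_equal(name_similarity(a, "phosphatasX"),
               name_similarity("phosphatasX", a))
})
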