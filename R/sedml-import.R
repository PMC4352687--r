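# SED-ML Level 1 to graph mapping.
#
# DOCUMENT -> hasSedml -> SEDML anchor node; model references, simulations
# and data generators hang off the anchor with BELONGS_TO back-edges, so a
# model reference or simulation reaches its document in exactly two
# BELONGS_TO hops and a data-generator variable in three. Tasks become
# SIMULATES edges simulation -> model reference; repeated tasks are
# flattened to their leaf tasks. Change elements are recorded as nodes on
# the model reference and later used to flag altered species.

#' Import a SED-ML simulation description into a property graph
#'
#' Accepts SED-ML Level 1 (Versions 1-2). Creates one
#' `SEDML_MODELREFERENCE` node per listed model (`MODELSOURCE` holds the
#' `source` attribute verbatim), one `SEDML_SIMULATION` node per
#' simulation (`SIMKISAO` from the algorithm's `kisaoID`), a
#' `SEDML_DATAGENERATOR` node per data generator with one
#' `SEDML_VARIABLE` node per variable (`TARGET` holds the XPath
#' verbatim), and `SIMULATES` edges derived from the task pairings.
#' Data-generator math is not interpreted.
#'
#' @param g A `property_graph`.
#' @param path Path to a SED-ML XML file.
#' @param filename Stored `FILENAME`; defaults to `basename(path)`.
#' @return Import report: `document_node`, `sedml_node`,
#'   `model_references` (data frame of node id and `MODELSOURCE`),
#'   `simulations` (node id and `SIMKISAO`), `datagenerators` and
#'   `changes` counts.
#' @export
import_sedml <- function(g, path, filename = basename(path)) {
  doc <- xml2::read_xml(path)
  ns <- unlist(xml2::xml_ns(doc))
  if (xml2::xml_name(doc) != "sedML" || !any(grepl("sed-?ml\\.org", ns)))
    stop("not a SED-ML document: ", filename)

  document <- pg_add_node(g, "DOCUMENT", list(FILENAME = filename))
  anchor <- pg_add_node(g, "SEDML", list())
  pg_add_edge(g, document, anchor, "hasSedml")
  pg_add_edge(g, anchor, document, "BELONGS_TO")

  refs <- list(); ref_rows <- list()
  changes <- 0L
  for (m in xchildren(doc, "listOfModels", "model")) {
    src <- xattr(m, "source")
    id <- xattr(m, "id")
    rid <- pg_add_node(g, "SEDML_MODELREFERENCE",
                       list(ID = id, MODELSOURCE = src))
    pg_add_edge(g, anchor, rid, "hasModelReference")
    pg_add_edge(g, rid, anchor, "BELONGS_TO")
    refs[[id]] <- rid
    ref_rows[[length(ref_rows) + 1L]] <- data.frame(
      node = rid, MODELSOURCE = src, stringsAsFactors = FALSE)
    for (lst in xchildren(m, "listOfChanges")) {
      for (ch in xml2::xml_children(lst)) {
        cn <- pg_add_node(g, "SEDML_CHANGE", list(
          TARGET = xattr(ch, "target"), KIND = xml2::xml_name(ch)))
        pg_add_edge(g, rid, cn, "hasChange")
        pg_add_edge(g, cn, rid, "BELONGS_TO")
        changes <- changes + 1L
      }
    }
  }

  sims <- list(); sim_rows <- list()
  for (s in xchildren(doc, "listOfSimulations")) {
    for (sim in xml2::xml_children(s)) {
      alg <- xchildren(sim, "algorithm")
      kisao <- if (length(alg)) xattr(alg[[1]], "kisaoID") else NULL
      if (is.null(kisao) || !grepl("^KISAO:\\d{7}$", kisao))
        stop("SED-ML import error: simulation '", xattr(sim, "id"),
             "' lacks a KISAO:NNNNNNN algorithm id")
      sid <- pg_add_node(g, "SEDML_SIMULATION",
                         list(ID = xattr(sim, "id"), SIMKISAO = kisao))
      pg_add_edge(g, anchor, sid, "hasSimulation")
      pg_add_edge(g, sid, anchor, "BELONGS_TO")
      sims[[xattr(sim, "id")]] <- sid
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        node = sid, SIMKISAO = kisao, stringsAsFactors = FALSE)
    }
  }

  # tasks pair simulations with model references; repeatedTask flattens
  tasks <- list()  # task id -> c(model id, simulation id)
  pairings <- list()
  task_nodes <- xchildren(doc, "listOfTasks")
  all_tasks <- if (length(task_nodes)) xml2::xml_children(task_nodes[[1]]) else list()
  for (t in all_tasks) {
    if (xml2::xml_name(t) == "task") {
      mref <- xattr(t, "modelReference"); sref <- xattr(t, "simulationReference")
      if (is.null(refs[[mref]]))
        stop("SED-ML import error: task references unknown model '", mref, "'")
      if (is.null(sims[[sref]]))
        stop("SED-ML import error: task references unknown simulation '", sref, "'")
      tasks[[xattr(t, "id")]] <- c(mref, sref)
      pairings[[length(pairings) + 1L]] <- c(mref, sref)
    }
  }
  for (t in all_tasks) {
    if (xml2::xml_name(t) == "repeatedTask") {
      for (st in xchildren(t, "listOfSubTasks", "subTask")) {
        leaf <- xattr(st, "task")
        if (is.null(tasks[[leaf]]))
          stop("SED-ML import error: repeatedTask references unknown task '",
               leaf, "'")
        pairings[[length(pairings) + 1L]] <- tasks[[leaf]]
      }
    }
  }
  seen <- character()
  for (p in pairings) {
    key <- paste(p, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    pg_add_edge(g, sims[[p[2]]], refs[[p[1]]], "SIMULATES")
  }

  task_model <- function(tid) if (!is.null(tasks[[tid]])) tasks[[tid]][1] else NULL

  ndg <- 0L
  for (dg in xchildren(doc, "listOfDataGenerators", "dataGenerator")) {
    dgn <- pg_add_node(g, "SEDML_DATAGENERATOR", list(ID = xattr(dg, "id")))
    pg_add_edge(g, anchor, dgn, "hasDataGenerator")
    pg_add_edge(g, dgn, anchor, "BELONGS_TO")
    ndg <- ndg + 1L
    for (v in xchildren(dg, "listOfVariables", "variable")) {
      tgt <- xattr(v, "target")
      tref <- xattr(v, "taskReference")
      vn <- pg_add_node(g, "SEDML_VARIABLE", c(
        list(ID = xattr(v, "id")),
        if (is.null(tgt)) list() else list(TARGET = tgt),
        if (is.null(tref) || is.null(task_model(tref))) list()
        else list(MODELREF = task_model(tref))))
      pg_add_edge(g, dgn, vn, "hasVariable")
      pg_add_edge(g, vn, dgn, "BELONGS_TO")
    }
  }

  structure(list(
    document_node = document, sedml_node = anchor,
    model_references = do.call(rbind, c(ref_rows, list(
      data.frame(node = integer(), MODELSOURCE = character())))),
    simulations = do.call(rbind, c(sim_rows, list(
      data.frame(node = integer(), SIMKISAO = character())))),
    datagenerators = ndg, changes = changes),
    class = "sedml_import_report")
}

#' @export
print.sedml_import_report <- function(x, ...) {
  cat("SED-ML import: document node", x$document_node, "\n")
  cat(nrow(x$model_references), "model reference(s),",
      nrow(x$simulations), "simulation(s),",
      x$datagenerators, "data generator(s),",
      x$changes, "change(s)\n")
  invisible(x)
}
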