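# Plain-text emitters for small SBML / CellML / SED-ML / OBO documents.
# Used by the synthetic-corpus generator and by the bundled reconstructions
# of published worked examples; output is deterministic (pure string
# assembly, LF line endings) so identical inputs give byte-identical files.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

rdf_annotation_block <- function(anns, meta_id, indent = "      ") {
  # anns: list of list(qualifier=, uris=)
  if (!length(anns)) return(character())
  ln <- c(paste0(indent, "<annotation>"),
          paste0(indent, "  <rdf:RDF",
                 " xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
                 " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\"",
                 " xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\">"),
          paste0(indent, "    <rdf:Description rdf:about=\"#", meta_id, "\">"))
  for (a in anns) {
    pre <- if (a$qualifier %in% c("isDescribedBy", "isDerivedFrom",
                                  "isInstanceOf")) "bqmodel" else "bqbiol"
    ln <- c(ln, paste0(indent, "      <", pre, ":", a$qualifier, ">"),
            paste0(indent, "        <rdf:Bag>"),
            paste0(indent, "          <rdf:li rdf:resource=\"",
                   xml_escape(a$uris), "\"/>"),
            paste0(indent, "        </rdf:Bag>"),
            paste0(indent, "      </", pre, ":", a$qualifier, ">"))
  }
  c(ln, paste0(indent, "    </rdf:Description>"),
    paste0(indent, "  </rdf:RDF>"),
    paste0(indent, "</annotation>"))
}

# species/parameters: data frames or lists of lists with fields
# id, name, compartment (species), anns (list of qualifier/uris)
emit_sbml <- function(path, model_id, model_name,
                      compartments = list(), species = list(),
                      parameters = list(), reactions = list(),
                      model_anns = list()) {
  ln <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
          paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\"",
                 " level=\"2\" version=\"4\">"),
          paste0("  <model id=\"", model_id, "\" name=\"",
                 xml_escape(model_name), "\" metaid=\"meta_", model_id, "\">"),
          rdf_annotation_block(model_anns, paste0("meta_", model_id),
                               indent = "    "))
  if (length(compartments)) {
    ln <- c(ln, "    <listOfCompartments>")
    for (cp in compartments) {
      anns <- cp$anns
      if (length(anns)) {
        ln <- c(ln, paste0("      <compartment id=\"", cp$id,
                           "\" name=\"", xml_escape(cp$name),
                           "\" metaid=\"meta_", cp$id, "\">"),
                rdf_annotation_block(anns, paste0("meta_", cp$id),
                                     indent = "        "),
                "      </compartment>")
      } else {
        ln <- c(ln, paste0("      <compartment id=\"", cp$id,
                           "\" name=\"", xml_escape(cp$name), "\"/>"))
      }
    }
    ln <- c(ln, "    </listOfCompartments>")
  }
  if (length(species)) {
    ln <- c(ln, "    <listOfSpecies>")
    for (sp in species) {
      head_ <- paste0("      <species id=\"", sp$id, "\" name=\"",
                      xml_escape(sp$name), "\" compartment=\"",
                      sp$compartment, "\" metaid=\"meta_", sp$id, "\"")
      if (length(sp$anns)) {
        ln <- c(ln, paste0(head_, ">"),
                rdf_annotation_block(sp$anns, paste0("meta_", sp$id),
                                     indent = "        "),
                "      </species>")
      } else ln <- c(ln, paste0(head_, "/>"))
    }
    ln <- c(ln, "    </listOfSpecies>")
  }
  if (length(parameters)) {
    ln <- c(ln, "    <listOfParameters>")
    for (pp in parameters) {
      head_ <- paste0("      <parameter id=\"", pp$id, "\" name=\"",
                      xml_escape(pp$name), "\" value=\"",
                      if (is.null(pp$value)) "1" else pp$value,
                      "\" metaid=\"meta_", pp$id, "\"")
      if (length(pp$anns)) {
        ln <- c(ln, paste0(head_, ">"),
                rdf_annotation_block(pp$anns, paste0("meta_", pp$id),
                                     indent = "        "),
                "      </parameter>")
      } else ln <- c(ln, paste0(head_, "/>"))
    }
    ln <- c(ln, "    </listOfParameters>")
  }
  if (length(reactions)) {
    ln <- c(ln, "    <listOfReactions>")
    for (rx in reactions) {
      ln <- c(ln, paste0("      <reaction id=\"", rx$id, "\" name=\"",
                         xml_escape(rx$name), "\" metaid=\"meta_", rx$id,
                         "\" reversible=\"false\">"),
              rdf_annotation_block(rx$anns, paste0("meta_", rx$id),
                                   indent = "        "))
      role_list <- function(tag, ids, ref_tag = "speciesReference") {
        if (!length(ids)) return(character())
        c(paste0("        <", tag, ">"),
          paste0("          <", ref_tag, " species=\"", ids, "\"/>"),
          paste0("        </", tag, ">"))
      }
      ln <- c(ln, role_list("listOfReactants", rx$reactants),
              role_list("listOfProducts", rx$products),
              role_list("listOfModifiers", rx$modifiers,
                        "modifierSpeciesReference"),
              "      </reaction>")
    }
    ln <- c(ln, "    </listOfReactions>")
  }
  ln <- c(ln, "  </model>", "</sbml>")
  writeLines(ln[nzchar(ln) | TRUE], path, useBytes = TRUE)
  invisible(path)
}

# components: list of list(name=, variables=character vector)
# connections: list of list(c1, c2, pairs = list(c(v1, v2), ...))
emit_cellml <- function(path, model_name, components = list(),
                        connections = list(), pubmed = NULL) {
  ln <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
          paste0("<model xmlns=\"http://www.cellml.org/cellml/1.0#\"",
                 " xmlns:cmeta=\"http://www.cellml.org/metadata/1.0#\"",
                 " name=\"", model_name, "\" cmeta:id=\"", model_name, "\">"))
  for (cp in components) {
    ln <- c(ln, paste0("  <component name=\"", cp$name, "\">"),
            paste0("    <variable name=\"", cp$variables,
                   "\" units=\"dimensionless\"/>"),
            "  </component>")
  }
  for (cn in connections) {
    ln <- c(ln, "  <connection>",
            paste0("    <map_components component_1=\"", cn$c1,
                   "\" component_2=\"", cn$c2, "\"/>"))
    for (p in cn$pairs)
      ln <- c(ln, paste0("    <map_variables variable_1=\"", p[1],
                         "\" variable_2=\"", p[2], "\"/>"))
    ln <- c(ln, "  </connection>")
  }
  if (!is.null(pubmed)) {
    ln <- c(ln,
      paste0("  <rdf:RDF",
             " xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
             " xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\">"),
      paste0("    <rdf:Description rdf:about=\"#", model_name, "\">"),
      "      <bqmodel:isDescribedBy>",
      "        <rdf:Bag>",
      paste0("          <rdf:li rdf:resource=\"", xml_escape(pubmed), "\"/>"),
      "        </rdf:Bag>",
      "      </bqmodel:isDescribedBy>",
      "    </rdf:Description>",
      "  </rdf:RDF>")
  }
  ln <- c(ln, "</model>")
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}

# models: list of list(id, source); sims: list of list(id, kisao);
# tasks: list of list(id, model, sim);
# datagens: list of list(id, task, target);
# changes: list of list(model, target)
emit_sedml <- function(path, models, sims, tasks, datagens = list(),
                       changes = list()) {
  ln <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
          paste0("<sedML xmlns=\"http://sed-ml.org/\" level=\"1\"",
                 " version=\"1\">"),
          "  <listOfSimulations>")
  for (s in sims)
    ln <- c(ln, paste0("    <uniformTimeCourse id=\"", s$id,
                       "\" initialTime=\"0\" outputStartTime=\"0\"",
                       " outputEndTime=\"100\" numberOfPoints=\"100\">"),
            paste0("      <algorithm kisaoID=\"", s$kisao, "\"/>"),
            "    </uniformTimeCourse>")
  ln <- c(ln, "  </listOfSimulations>", "  <listOfModels>")
  for (m in models) {
    chs <- Filter(function(ch) identical(ch$model, m$id), changes)
    head_ <- paste0("    <model id=\"", m$id,
                    "\" language=\"urn:sedml:language:xml\" source=\"",
                    xml_escape(m$source), "\"")
    if (length(chs)) {
      ln <- c(ln, paste0(head_, ">"), "      <listOfChanges>")
      for (ch in chs)
        ln <- c(ln, paste0("        <changeAttribute target=\"",
                           xml_escape(ch$target),
                           "\" newValue=\"1\"/>"))
      ln <- c(ln, "      </listOfChanges>", "    </model>")
    } else ln <- c(ln, paste0(head_, "/>"))
  }
  ln <- c(ln, "  </listOfModels>", "  <listOfTasks>")
  for (t in tasks)
    ln <- c(ln, paste0("    <task id=\"", t$id, "\" modelReference=\"",
                       t$model, "\" simulationReference=\"", t$sim, "\"/>"))
  ln <- c(ln, "  </listOfTasks>")
  if (length(datagens)) {
    ln <- c(ln, "  <listOfDataGenerators>")
    for (d in datagens)
      ln <- c(ln, paste0("    <dataGenerator id=\"", d$id, "\">"),
              "      <listOfVariables>",
              paste0("        <variable id=\"", d$id,
                     "_v\" taskReference=\"", d$task, "\" target=\"",
                     xml_escape(d$target), "\"/>"),
              "      </listOfVariables>",
              "    </dataGenerator>")
    ln <- c(ln, "  </listOfDataGenerators>")
  }
  ln <- c(ln, "</sedML>")
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}

# terms: list of list(id, name, def, parents = character())
emit_obo <- function(path, terms, ontology_name = "synthetic") {
  ln <- c("format-version: 1.2",
          paste0("ontology: ", ontology_name), "")
  for (t in terms) {
    ln <- c(ln, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.null(t$def))
      ln <- c(ln, paste0("def: \"", t$def, "\" []"))
    for (p in t$parents) ln <- c(ln, paste0("is_a: ", p))
    ln <- c(ln, "")
  }
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}
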