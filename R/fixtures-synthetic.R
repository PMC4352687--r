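# Seeded synthetic corpus generator. Emulates the shape of public model
# repositories at desk scale: multi-entity SBML reaction networks with
# MIRIAM annotations, CellML twin models sharing a reference publication
# with controlled name perturbation, SED-ML files referencing the stored
# models, and a mini ontology. Everything planted is recorded in a ground
# truth the import/link invariant tests compare against.

#' Specification for a synthetic corpus
#'
#' @param seed RNG seed; identical specs produce byte-identical files.
#' @param n_models Number of SBML models.
#' @param species_range,reaction_range,compartment_range Integer intervals
#'   `c(lo, hi)` sampled per model.
#' @param annotation_density Probability in `[0, 1]` that a species or
#'   parameter carries an ontology annotation.
#' @param twin_fraction Fraction of models that get a CellML twin sharing
#'   the reference publication.
#' @param name_perturbation Edit-distance budget applied to twin entity
#'   names (0 = exact copies).
#' @param ontology_shape `c(depth, branching)` of the complete mini
#'   ontology tree.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_models = 3L,
                           species_range = c(5L, 10L),
                           reaction_range = c(2L, 5L),
                           compartment_range = c(1L, 2L),
                           annotation_density = 0.6,
                           twin_fraction = 0.5,
                           name_perturbation = 1L,
                           ontology_shape = c(3L, 2L)) {
  if (twin_fraction > 0 && n_models < 1L)
    stop("twin_fraction > 0 requires at least one model")
  stopifnot(annotation_density >= 0, annotation_density <= 1,
            twin_fraction >= 0, twin_fraction <= 1,
            species_range[1] >= 1, species_range[2] >= species_range[1])
  structure(list(seed = as.integer(seed), n_models = as.integer(n_models),
                 species_range = species_range,
                 reaction_range = reaction_range,
                 compartment_range = compartment_range,
                 annotation_density = annotation_density,
                 twin_fraction = twin_fraction,
                 name_perturbation = as.integer(name_perturbation),
                 ontology_shape = ontology_shape),
            class = "synthetic_spec")
}

# pronounceable consonant-vowel names so edit perturbations stay readable
# and meaningful for Levenshtein scoring
random_name <- function(n_syllables = sample(2:4, 1)) {
  cons <- strsplit("bdfgklmnprstvz", "")[[1]]
  vow <- strsplit("aeiou", "")[[1]]
  paste0(paste0(sample(cons, n_syllables, TRUE),
                sample(vow, n_syllables, TRUE)), collapse = "")
}

unique_names <- function(n, taken = character()) {
  out <- character()
  while (length(out) < n) {
    nm <- random_name()
    if (!(nm %in% c(out, taken))) out <- c(out, nm)
  }
  out
}

# apply `budget` single-character substitutions, rejection-sampling so the
# perturbed name never collides with any other entity's name
perturb_name <- function(name, budget, taken) {
  if (budget == 0L) return(name)
  alpha <- strsplit("abcdefghiklmnoprstuvz", "")[[1]]
  repeat {
    out <- strsplit(name, "")[[1]]
    pos <- sample(seq_along(out), min(budget, length(out)))
    for (p_ in pos) out[p_] <- sample(setdiff(alpha, out[p_]), 1)
    out <- paste0(out, collapse = "")
    if (!(out %in% taken)) return(out)
  }
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic corpus of model, simulation and ontology files
#'
#' Emits well-formed SBML, CellML and SED-ML files plus a mini OBO
#' ontology honouring the spec, together with a ground truth recording
#' every planted fact: per-document entity counts, annotation targets,
#' SED-ML reference and observation targets, changed species and
#' cross-format twin correspondences. Twins share a synthetic PubMed
#' publication resource.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @return List with `files` (named paths) and `truth` (ground-truth
#'   list).
#' @export
generate_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    depth <- spec$ontology_shape[1]; branch <- spec$ontology_shape[2]
    terms <- list(); idx <- 0L
    build <- function(parent, level) {
      for (b in seq_len(branch)) {
        idx <<- idx + 1L
        id <- sprintf("SYN:%07d", idx)
        terms[[length(terms) + 1L]] <<- list(
          id = id, name = random_name(),
          def = paste("synthetic concept", idx),
          parents = if (is.null(parent)) character() else parent)
        if (level < depth) build(id, level + 1L)
      }
    }
    build(NULL, 1L)
    onto_path <- file.path(dir, "mini-ontology.obo")
    emit_obo(onto_path, terms, "synthetic-ontology")
    concept_ids <- vapply(terms, `[[`, character(1), "id")

    files <- c(ontology = onto_path)
    truth <- list(ontology = list(concepts = length(terms)),
                  documents = list(), twins = list(), sedml = list())
    n_twins <- round(spec$twin_fraction * spec$n_models)
    taken <- character()

    for (i in seq_len(spec$n_models)) {
      n_sp <- sample(spec$species_range[1]:spec$species_range[2], 1)
      n_rx <- sample(spec$reaction_range[1]:spec$reaction_range[2], 1)
      n_cp <- sample(spec$compartment_range[1]:spec$compartment_range[2], 1)
      sp_names <- unique_names(n_sp, taken); taken <- c(taken, sp_names)
      model_id <- sprintf("synmod%03d", i)
      model_name <- paste0("model_", random_name())
      pubmed <- sprintf("urn:miriam:pubmed:9%06d", i)
      comps <- lapply(seq_len(n_cp), function(k) list(
        id = sprintf("c%d_%d", i, k), name = sprintf("c%d_%d", i, k),
        anns = list()))
      planted_ann <- list()
      species <- lapply(seq_len(n_sp), function(k) {
        anns <- list()
        if (stats::runif(1) < spec$annotation_density) {
          cid <- sample(concept_ids, 1)
          anns <- list(list(qualifier = "isVersionOf",
                            uris = sprintf("urn:miriam:syn:%s",
                                           sub(":", "%3A", cid))))
          planted_ann[[length(planted_ann) + 1L]] <<- list(
            element = sp_names[k], concept = cid)
        }
        list(id = sp_names[k], name = sp_names[k],
             compartment = comps[[sample(n_cp, 1)]]$id, anns = anns)
      })
      reactions <- lapply(seq_len(n_rx), function(k) {
        parts <- sample(sp_names, min(3, n_sp))
        list(id = sprintf("r%d_%d", i, k), name = sprintf("r%d_%d", i, k),
             reactants = parts[1],
             products = if (length(parts) > 1) parts[2] else character(),
             modifiers = if (length(parts) > 2) parts[3] else character(),
             anns = list())
      })
      sbml_file <- file.path(dir, sprintf("%s.sbml.xml", model_id))
      emit_sbml(sbml_file, model_id, model_name, comps, species,
                parameters = list(), reactions = reactions,
                model_anns = list(list(qualifier = "isDescribedBy",
                                       uris = pubmed)))
      files[[sprintf("sbml_%d", i)]] <- sbml_file
      truth$documents[[basename(sbml_file)]] <- list(
        format = "sbml", model_id = model_id, model_name = model_name,
        species = sp_names, n_species = n_sp, n_reactions = n_rx,
        n_compartments = n_cp, pubmed = pubmed,
        annotations = planted_ann)

      if (i <= n_twins) {
        twin_name <- paste0(model_name, "_cellml")
        pert <- stats::runif(n_sp) < 0.5
        comp_names <- character(n_sp)
        for (k in seq_len(n_sp)) {
          comp_names[k] <- if (pert[k])
            perturb_name(sp_names[k], spec$name_perturbation,
                         c(taken, comp_names)) else sp_names[k]
        }
        taken <- c(taken, setdiff(comp_names, sp_names))
        cl_comps <- c(
          list(list(name = "environment", variables = "time")),
          lapply(seq_len(n_sp), function(k)
            list(name = comp_names[k], variables = c("time", comp_names[k]))))
        conns <- lapply(seq_len(n_sp), function(k) list(
          c1 = comp_names[k], c2 = "environment",
          pairs = list(c("time", "time"))))
        cellml_file <- file.path(dir, sprintf("%s.cellml", model_id))
        emit_cellml(cellml_file, twin_name, cl_comps, conns, pubmed)
        files[[sprintf("cellml_%d", i)]] <- cellml_file
        truth$documents[[basename(cellml_file)]] <- list(
          format = "cellml", model_name = twin_name,
          n_components = n_sp + 1L,
          n_variables = 1L + 2L * n_sp,
          n_connections = n_sp, pubmed = pubmed)
        truth$twins[[length(truth$twins) + 1L]] <- list(
          sbml = basename(sbml_file), cellml = basename(cellml_file),
          pairs = data.frame(sbml_name = sp_names,
                             cellml_name = comp_names,
                             perturbed = pert,
                             stringsAsFactors = FALSE))
      }

      observed <- sample(sp_names, min(2, n_sp))
      changed <- sp_names[1]
      sed_file <- file.path(dir, sprintf("%s.sedml.xml", model_id))
      kisao <- sample(c("KISAO:0000019", "KISAO:0000030"), 1)
      emit_sedml(sed_file,
        models = list(list(id = "m1", source = basename(sbml_file))),
        sims = list(list(id = "sim1", kisao = kisao)),
        tasks = list(list(id = "t1", model = "m1", sim = "sim1")),
        datagens = lapply(seq_along(observed), function(k) list(
          id = sprintf("dg%d", k), task = "t1",
          target = sprintf(
            "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='%s']",
            observed[k]))),
        changes = list(list(model = "m1", target = sprintf(
          "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='%s']",
          changed))))
      files[[sprintf("sedml_%d", i)]] <- sed_file
      truth$sedml[[basename(sed_file)]] <- list(
        references = basename(sbml_file), kisao = kisao,
        observed = observed, changed = changed)
    }
    list(files = files, truth = truth)
  })
}

#' Generate one controlled cross-format twin pair
#'
#' One SBML model and one CellML model sharing a synthetic publication,
#' with a controlled mix of entity pairs: `n_exact` identical names,
#' `n_perturbed` names at a fixed edit distance (these pairs additionally
#' share an ontology annotation on both sides), and `n_decoys` unrelated
#' entities on each side whose names differ by at least 60% of their
#' length. Used to measure the cross-format matcher's recall and
#' false-link behaviour against known ground truth.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param n_exact,n_perturbed,n_decoys Pair counts.
#' @param perturb_dist Edit distance applied to perturbed names.
#' @param shared_publication If `FALSE`, the two models cite different
#'   publications (no links must ever be created).
#' @return List with `sbml`, `cellml` file paths and `truth` (planted
#'   pairs and decoy names).
#' @export
generate_twin_pair <- function(dir, seed = 1L, n_exact = 10L,
                               n_perturbed = 5L, n_decoys = 5L,
                               perturb_dist = 1L,
                               shared_publication = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    n <- n_exact + n_perturbed
    names_ <- unique_names(n + 2L * n_decoys)
    base <- names_[seq_len(n)]
    decoy_s <- names_[n + seq_len(n_decoys)]
    decoy_c <- names_[n + n_decoys + seq_len(n_decoys)]
    # decoy counterparts must sit at >= 60% of length in edit distance
    ok_decoy <- function(a, b) {
      utils::adist(a, b)[1, 1] >= ceiling(0.6 * max(nchar(a), nchar(b)))
    }
    for (k in seq_len(n_decoys)) {
      while (!all(vapply(c(decoy_s, base), ok_decoy, logical(1),
                         b = decoy_c[k])))
        decoy_c[k] <- unique_names(1, c(names_, decoy_c))
    }
    cellml_names <- base
    taken <- c(names_, decoy_c)
    if (n_perturbed > 0) {
      for (k in n_exact + seq_len(n_perturbed)) {
        cellml_names[k] <- perturb_name(base[k], perturb_dist, taken)
        taken <- c(taken, cellml_names[k])
      }
    }
    pub_s <- "urn:miriam:pubmed:9000001"
    pub_c <- if (shared_publication) pub_s else "urn:miriam:pubmed:9000002"
    shared_uri <- function(k) sprintf("urn:miriam:syn:SYN%%3A%07d", k)

    species <- lapply(seq_len(n), function(k) list(
      id = base[k], name = base[k], compartment = "cell",
      anns = if (k > n_exact)
        list(list(qualifier = "isVersionOf", uris = shared_uri(k)))
      else list()))
    species <- c(species, lapply(seq_len(n_decoys), function(k) list(
      id = decoy_s[k], name = decoy_s[k], compartment = "cell",
      anns = list())))
    sbml_file <- file.path(dir, "twin.sbml.xml")
    emit_sbml(sbml_file, "twinmodel", "twin_model",
              compartments = list(list(id = "cell", name = "cell",
                                       anns = list())),
              species = species,
              model_anns = list(list(qualifier = "isDescribedBy",
                                     uris = pub_s)))

    comps <- lapply(seq_len(n), function(k) list(
      name = cellml_names[k], variables = c("time", cellml_names[k])))
    comps <- c(comps, lapply(seq_len(n_decoys), function(k) list(
      name = decoy_c[k], variables = "time")))
    cellml_file <- file.path(dir, "twin.cellml")
    emit_cellml(cellml_file, "twin_model_cellml", comps,
                connections = list(), pubmed = pub_c)
    # annotations on the CellML side: add RDF blocks for perturbed comps
    if (n_perturbed > 0) {
      txt <- readLines(cellml_file, warn = FALSE)
      extra <- c(
        paste0("  <rdf:RDF",
               " xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
               " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">"),
        unlist(lapply(n_exact + seq_len(n_perturbed), function(k) c(
          paste0("    <rdf:Description rdf:about=\"#meta_",
                 cellml_names[k], "\">"),
          "      <bqbiol:isVersionOf>",
          "        <rdf:Bag>",
          paste0("          <rdf:li rdf:resource=\"", shared_uri(k), "\"/>"),
          "        </rdf:Bag>",
          "      </bqbiol:isVersionOf>",
          "    </rdf:Description>"))),
        "  </rdf:RDF>")
      txt <- append(txt, extra, after = length(txt) - 1L)
      # give the perturbed components a cmeta:id the RDF can point at
      for (k in n_exact + seq_len(n_perturbed)) {
        txt <- sub(
          paste0("<component name=\"", cellml_names[k], "\">"),
          paste0("<component name=\"", cellml_names[k],
                 "\" cmeta:id=\"meta_", cellml_names[k], "\">"),
          txt, fixed = TRUE)
      }
      writeLines(txt, cellml_file, useBytes = TRUE)
    }
    truth <- list(
      pairs = data.frame(
        sbml_name = base, cellml_name = cellml_names,
        perturbed = c(rep(FALSE, n_exact), rep(TRUE, n_perturbed)),
        stringsAsFactors = FALSE),
      decoys_sbml = decoy_s, decoys_cellml = decoy_c,
      shared_publication = shared_publication)
    list(sbml = sbml_file, cellml = cellml_file, truth = truth)
  })
}
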