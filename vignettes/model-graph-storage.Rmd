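---
title: "Storing and linking computational-biology models as a property graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and linking computational-biology models as a property graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modelgraph)
```

## Why a graph store for models

Public model repositories hold computational models of biological systems
in XML formats: SBML encodes reaction networks (species, reactions,
compartments, parameters), CellML encodes networks of components whose
variables are wired together by connections, and SED-ML describes
simulation experiments — which models to simulate, with which algorithm
(identified by a KiSAO term) and which variables to observe. Around the
model code sits heterogeneous meta-data: MIRIAM-style semantic annotations
that tie model entities to terms in bio-ontologies (SBO, GO, ChEBI,
KiSAO) via qualifier relations (`is`, `isVersionOf`, `hasPart`,
`isDescribedBy`), and reference publications. Relational schemas fit this
data poorly; a model *is* a network, so `modelgraph` stores it as one: a
labelled property graph in which every document, model, species,
reaction, component, variable, simulation, annotation, resource and
ontology concept is a node, and every structural or semantic relation is
a typed directed edge.

## The graph schema

Each imported file gets a `DOCUMENT` root node; a `hasModel` edge leads
to the model node and model entities hang off it (`hasSpecies`,
`hasReaction`, `hasCompartment`, `hasComponent`, `hasVariable`, ...).
Every created node also points *upward* to its parent with a
`BELONGS_TO` edge, so any entity reaches its document by following
`BELONGS_TO` edges and a simulation or model reference sits exactly two
hops below its SED-ML document. Reaction roles are directed edges from
the species to the reaction (`IS_REACTANT`, `IS_PRODUCT`,
`IS_MODIFIER`); a species located in a compartment carries one
`isContainedIn` edge.

Annotations use a fixed direction convention chosen so that every query
shape the package documents holds simultaneously:

* element `-[hasAnnotation]->` `ANNOTATION`
* `ANNOTATION -[BELONGS_TO]->` element
* `ANNOTATION -[<qualifier>]->` `RESOURCE`
* `RESOURCE -[BELONGS_TO]->` `ANNOTATION`

A `RESOURCE` node is created once per distinct URI. URIs are normalized
before deduplication: the MIRIAM URN `urn:miriam:obo.go:GO%3A0005892`
and the URL `http://identifiers.org/go/GO:0005892` collapse to one key
(percent-decoding, case-folded collection tag, `obo.` prefix dropped).
PubMed resources additionally carry the `PUBLICATION` label; because
they are deduplicated like any resource, two encodings of the same model
citing the same paper automatically share one publication node — the
fact the cross-format linker later exploits.

Ontologies imported from OBO 1.2 or an OWL-XML subset become concept
nodes labelled `<tag>Ontology` with `isA` edges child to parent. Only
`isA` is mapped; other relationship types and cross-ontology references
are counted and dropped, and a cyclic `isA` graph aborts the import.
`descendants()` is the transitive closure downward, self included, which
is all the subsumption the supported queries need — no description-logic
reasoning is performed.

## The four link types

Three link types are *explicit* — derivable from what the files encode —
and always carry confidence 1:

(a) **Annotation to ontology concept.** A resource whose URI contains
the ontology tag and whose last seven characters equal the last seven
characters of a concept id gains an `IS_ONTOLOGY_ENTRY` edge. Seven is
the width of the zero-padded SBO/GO/KiSAO accessions, so one rule covers
all three ontologies; a resource matching two concepts is an error,
never a silent pick. Linking also appends the concept's label and
definition to the resource's description text, which feeds the full-text
index.

(b) **SED-ML to model.** Model references resolve against stored
documents in a fixed order — exact filename, then model ID, then
basename — first hit wins and ambiguity is reported, not guessed.

(c) **Data generator to entity.** A variable whose XPath target names an
entity by `@id` or `@name` equality (the dialect SED-ML uses in practice
on SBML and CellML) gains an `OBSERVES` edge into the model its task
references; change targets flag the species with `IS_CHANGED`. XPath
outside this subset is reported unresolved rather than mis-linked.

(d) **Cross-format entity links** are *implicit* and scored. Only model
pairs of different formats that share a publication resource are
considered at all — without that gate, no name similarity ever creates a
link. For each cross-product pair of named entities (SBML species,
compartments, parameters against CellML components and variables) the
score is

```
score = 0.7 * sim + 0.3 * ann
sim   = 1 - levenshtein(fold(a), fold(b)) / max(nchar(fold(a)), nchar(fold(b)))
ann   = 1 if the entities share a normalized annotation resource, else 0
```

where `fold()` case-folds and applies a light Porter-style suffix
stripper (plural/`ed`/`ing` forms; short tokens untouched). The 0.7/0.3
weighting, the stemmer, the default threshold 0.7 and the best-match
filter are this package's choices — the linking idea itself fixes only
the ingredients (shared publication, name similarity, annotation
overlap) — and all are configurable arguments. Each entity keeps only
its best-scoring counterpart (ties broken lexicographically by
counterpart name; a pair survives if it is the best for at least one of
its endpoints), the symmetric edge is stored once with the score as its
`confidence` attribute, and re-running any linker creates no duplicate
edges. An `IS_SIMILAR_TO` edge asserts similarity, never equality of the
models.

## Queries

The query layer is a programmatic pattern API plus named canned queries
rather than a query-language parser: the contribution worth re-building
is the schema and its semantics, not a host syntax. `pg_match()`
evaluates a list of steps (label + attribute filters, then typed
directed hops with bounds, optionally negated) by index-seeded
traversal with breadth-first minimal-hop semantics and a visited set, so
variable-length patterns are cycle-safe. Rows are sorted by node id,
making results deterministic. Aggregation supports `count`, `min`,
`max`, `avg`, `stdev` and distinct collection with ordering and limits;
`stdev` is the sample standard deviation (n−1 denominator) — the
statistics queries do not say which variant they report, and the sample
form is the defensible default for a corpus treated as a sample.

Ranked retrieval over annotation text is TF-IDF with log-scaled term
frequency (`1 + log tf`) and `log(N/df)` inverse document frequency,
conjunctive token semantics, ties broken by URI. This is a documented
simplification of a full ranked-retrieval engine; it is enough to
reproduce index look-ups such as finding all resources described as
"m-phase inducer phosphatase". Descriptive text for non-ontology
resources (UniProt, InterPro, EC) comes from a tab-separated
resource-description table loaded at build time, standing in for live
web look-ups so everything runs offline.

## Synthetic data: what it emulates, what it does not

`generate_corpus()` emits SBML reaction networks with MIRIAM
annotations, CellML twins sharing a synthetic PubMed publication with
controlled name perturbation, SED-ML files referencing the emitted
models, and a mini ontology — with a ground-truth record of every
planted fact. Defaults are desk-scale: 3 models of 5–10 species, 2–5
reactions and 1–2 compartments each, annotation density 0.6, half the
models twinned, an edit budget of one character per perturbed twin name,
and a depth-3 branching-2 ontology. Names come from a pronounceable
consonant-vowel generator so a one-character perturbation is a
meaningful Levenshtein signal, and perturbed names are
rejection-sampled against collisions. `generate_twin_pair()` plants the
controlled matcher benchmark: ten exact-name pairs, five pairs at edit
distance one (annotated identically on both sides, as genuinely
corresponding entities would be), and five decoys per side at a name
distance of at least 60% of the name length.

The generator reproduces the *mechanics* of repository data — structure,
annotations, cross-references — not its content: kinetics are
placeholders, annotation URIs point into a synthetic ontology, and the
name-length distribution is narrower than in curated models. Passing
tests therefore demonstrate that import, linking and querying are exact
on known ground truth, not that real curated corpora would yield any
particular statistics. Corpus-wide numbers (annotation frequency ranks,
per-model annotation statistics) depend on a specific repository release
and are computed by the package on whatever store it is given; the
bundled worked examples are synthetic reconstructions built from
published per-model results (species id lists, component names, printed
counts), clearly labelled `-synthetic` in their filenames.

## Numerical and degenerate-input choices

* Node ids are store-assigned increasing integers, stable within a
  session only; re-imports are compared up to isomorphism.
* `pg_traverse()` reports nodes by minimal hop distance; the start set
  is at distance 0 and is only included when `min_hops = 0`.
* Regex attribute filters are unanchored and case-sensitive, matching
  the `.*GO.*0005892` idiom.
* Duplicate reaction roles collapse to one edge with summed
  stoichiometry; self-edges are legal but flagged by `pg_validate()`.
* A species without a compartment attribute simply has no
  `isContainedIn` edge; models without annotations contribute no row to
  per-model annotation statistics (pattern-match semantics).
* Unknown annotation qualifiers become generic edges plus a warning;
  unit definitions are skipped and reported; SBML `comp`/`fbc` packages
  and CellML 1.2+/2.0 are rejected or ignored with explicit messages.
* The store serializes to a versioned JSON file; indices (label,
  resource-deduplication, ontology registry, concept, text) are rebuilt
  on load.

## Problem sizes

The test suite and the acceptance script run everything at desk scale:
pattern-matcher equivalence against exhaustive enumeration on 50 seeded
graphs of up to 40 nodes, descendant closure against depth-first search
on a 200-node random DAG, import round-trips over 100 seeded synthetic
models, and the matcher benchmark above. These sizes make exhaustive
oracles exact while keeping a full run in well under a minute.

## Known limitations

Single writer, no transactions, no server protocol or concurrent
access; no general query-language parser and no recursive path
expressions beyond single-type variable-length hops; CellML 1.1 imports
are flattened component lists (no encapsulation hierarchy); MathML is
stored verbatim, never interpreted; ontology cross-references and
non-`isA` relations are not mapped; models are never merged or declared
equal — cross-format links assert similarity with a stated confidence,
nothing more.
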