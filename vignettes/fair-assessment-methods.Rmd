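---
title: "Assessing FAIR maturity from embedded metadata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing FAIR maturity from embedded metadata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faircheckr)
```

## The assessment model

`faircheckr` treats FAIRness as a property of a resource's machine-readable
metadata. The unit of assessment is an *annotated resource*: a subject URL
(or dump key) plus the RDF graph harvested for it. Assessment has five
stages — harvest, optional knowledge-graph enrichment, metric evaluation,
profile validation, reporting — and each stage is a pure function of its
inputs, which is what makes offline runs byte-reproducible.

The central assumption is that embedded annotations (JSON-LD, RDFa,
microdata) and native RDF dumps are the ground truth about a resource.
The package does not infer metadata from page text, does not follow
`sameAs` chains, and does not attempt entity disambiguation.

## The twelve metrics and their semantics

Each metric is a boolean test; there are no partial scores. Priorities
(essential / important / useful) are reported but never weight an outcome.

| id | test | kind |
|------|------------------------------------------------------------|------|
| F1A | subject URL is a syntactically valid absolute URI | structure |
| F1B | an identifier property is present, **or** the subject URL uses a persistent scheme (DOI, identifiers.org, purl.\*, w3id.org) | property |
| F2A | the harvested graph is non-empty | structure |
| F2B | at least one used term is known to a vocabulary registry | registry |
| A1.1 | open protocol (http/https/ftp) and the resource resolved | protocol |
| A1.2 | an access-policy property is present (odrl/dct/dcat lists, plus `schema:downloadUrl`) | property |
| I1 | at least one triple came from a standard RDF syntax | structure |
| I2 | **every** used namespace is known to a registry | registry |
| I3 | some non-`rdf:type` triple points to an IRI under a different authority | reference |
| R1.1 | a license property is present (schema/dct/doap/dbo/cc/xhv/sto/nie) | property |
| R1.2 | a provenance property is present (PROV, PAV, DC terms, schema authorship) | property |
| R1.3 | a domain-registry term is used, **or** a community profile matches with zero violations | registry |

Points worth calling out:

* **Property metrics run through generated SPARQL.** One ASK template is
  instantiated per metric with a `VALUES ?p { ... }` clause enumerating
  the target properties (`build_values_ask()`); the evaluator answers true
  iff some predicate of the graph is in the list. The linear-scan oracle
  used in tests recomputes the same existential independently of the query
  path.
* **F1B is a disjunction.** Whether a persistent *identifier property*
  or a persistent *URL itself* should satisfy the principle is genuinely
  ambiguous; the package accepts either and records which route fired in
  the result log.
* **I2 is the one universally-quantified metric**: a single unregistered
  namespace fails it. Consequently the monotonicity property ("adding
  triples never flips a metric pass→fail") holds for augmentations drawn
  from registered vocabularies — the realistic enrichment scenario, and
  the one the property suites generate — but not for arbitrary triples.
  This is by design: diluting metadata with unregistered vocabularies
  *should* degrade the interoperability verdict.
* **A1.1 on dumps.** Resources loaded from an RDF dump carry no HTTP
  status; the package counts successfully retrieved-and-parsed dump
  content as "resolved" and then requires only an open-protocol scheme on
  the key. Fetched resources need a terminal status below 400.
* **F2A and I1** share their evidence (a non-empty graph from a standard
  syntax) but stay distinct metrics with distinct recommendations.
* **Twelve is the canonical set.** A1.2 is scored alongside the eleven
  classically tabled principles because access-policy properties are
  testable the same way; its priority is set to *important*. A2
  (long-term preservation) and F3 are out of scope — neither is testable
  from embedded metadata alone.

Alternative implementations of any metric can be registered
(`register_metric_impl()`) and selected per run; the canonical set stays
the default, and a failing implementation yields an `error` status for
that metric only.

## Vocabulary registries

`used_terms()` defines a graph's vocabulary footprint: all predicates,
plus all IRI objects of `rdf:type`. Blank nodes and literals never count;
the serialization-infrastructure namespaces (rdf, rdfs, owl, xsd) are
whitelisted and excluded from coverage denominators.

The default backends are local catalog snapshots shipped with the package
(a general catalog covering Schema.org, Dublin Core, DCAT, PROV, PAV and
the license vocabularies; a life-science catalog covering EDAM and OBO),
matched at namespace level. Term-level matching activates when a catalog
lists explicit terms. Live registry clients (LOV/OLS/BioPortal-style) can
be plugged in through the same `term_catalog` interface; the offline
default keeps every assessment hermetic and deterministic.

## Knowledge-graph enrichment

Enrichment generates one DESCRIBE query per (endpoint, identifier) pair:
nodes cross-referenced to the identifier through the endpoint's bridge
property (Wikidata's DOI property P356, OpenAIRE's persistent-id
property, the DataCite identifier bridge) are described and the result is
unioned into the resource graph. DOIs are normalized first — resolver
host and `doi:` prefix stripped, case-folded — so the same article
matches regardless of how the page spelled its DOI.

Enrichment is **off by default** and transports are pluggable: the
fixture transport answers queries from canned Turtle files keyed by the
SHA-1 of the exact query text, which makes enrichment tests and offline
runs fully deterministic. Two cache layers mirror realistic service use:
resource metadata for 60 seconds, registry answers for 14 days; keys are
the exact query text. Enrichment runs *before* metric evaluation, so
retrieved triples count as evidence; set union guarantees it never
removes anything, and a failing endpoint is logged and skipped.

## Profiles and generated SHACL shapes

A community profile lists properties by *marginality*. The mapping to
SHACL is fixed: minimum → property shape with `sh:severity sh:Violation`,
recommended → `sh:Warning`, optional → parsed but unshaped (an
Info-severity shape would change what "conformant" means). Every
constraint is a presence check (`sh:minCount 1`); cardinality upper
bounds are deliberately out of scope. All shapes are instantiated from a
single template, in sorted property order, so a fixed profile always
yields byte-identical Turtle — emitted shapes diff cleanly.

Profile selection honors the provider's own `dct:conformsTo` declaration
first; otherwise the entity's `rdf:type` is matched against profile
target classes. Ties go to the profile with more minimum properties
already present, then to the lexicographically first name. One best
profile is selected per entity; multi-profile reporting was considered
and rejected because "conformance" would no longer be a single flag.

Validation reports are deterministic tibbles; `humanize()` phrases
violations as requirements ("must be provided") and warnings as
improvements ("should be provided"), naming the entity and the missing
property in prefixed form. *Completeness* of an entity is
`(|recommended| − warnings) / |recommended|`; a profile with no
recommended properties scores 1 with a flag. Batch-level mean
completeness averages over entities (not over properties) — with
per-entity denominators equal, the two coincide.

## The synthetic-data generators

The fixtures module is first-class, tested code; it emulates the study
conditions so that every other module is testable with no network.

* **Pages.** A recipe (syntax × property groups) implies an exact triple
  set; the generated page extracts back to that set — the round-trip law
  is tested per syntax. The annotated-tool recipe mirrors a realistic
  software landing page: all ComputationalTool minimum and recommended
  properties, a DOI-valued `schema:identifier`, EDAM topic/operation/data
  IRIs, one download URL, and deliberately no license and no provenance,
  which pins the expected 10-of-12 outcome. The fixture profiles (Gene:
  identifier+name minimum, description+url recommended; ComputationalTool:
  name/description/url minimum, seven software descriptors recommended)
  are frozen synthetic copies shipped in `inst/extdata/profiles/`; their
  recommended sets exclude license so the prescribed worked-example
  outcome is internally consistent.
* **Batches.** `make_batch()` constructs `n` dump resources realizing
  prescribed 12-bit metric vectors and records them in a ledger. Dump
  resources obey structural constraints (`achievable_metric_vector()`
  documents them): every resource carries its type triple, so F2A and I1
  always pass; any registered-vocabulary property implies F2B; a
  relative key fails F1A and A1.1 together. Probability-driven batches
  draw per-metric Bernoulli flags and close them under these constraints,
  so recovery tests compare against the closed expectation (e.g. the
  realized R1.1 rate is P(F2B)·p(R1.1)). Ledger vectors correspond to
  `batch_config()` — offline, no profile fallback for R1.3 — so the
  R1.3 bit is controlled purely by EDAM-term usage.
* **Serving.** Worked examples run against an ephemeral local HTTP server
  (a background R process), so protocol behaviour — status codes,
  redirects, A1.1 — is exercised over a real transport rather than
  simulated.

What the generators do **not** emulate: malformed real-world markup
beyond tolerant HTML parsing, content negotiation, JavaScript-rendered
annotations (a renderer can be plugged into `fetch()`, none ships),
registry drift, and endpoint latency. Passing tests therefore demonstrate
correctness of the assessment logic on well-formed inputs, not robustness
against the long tail of the open web.

## Numerical and procedural choices

* **Determinism.** All randomized generators take explicit seeds;
  serializers emit sorted triples; reports exclude timestamps. Two
  offline runs on identical inputs produce byte-identical outputs.
* **HTTP.** Up to 10 redirects, 30 s timeout, a descriptive user agent;
  non-2xx terminal statuses are recorded, not raised. Client-side
  rendering is off by default and requires an explicit renderer.
* **Parsing tolerance.** HTML is parsed leniently; a malformed JSON-LD
  block is skipped with a warning and never aborts the other blocks.
  Blank-node labels are scoped per annotation block, so identical blank
  structures in different blocks never merge. `http://schema.org/` IRIs
  are normalized to the `https://` form so either spelling evaluates
  identically. The Turtle/JSON-LD/RDF-XML readers cover the documented
  subsets the package emits plus the common constructs of hand-written
  files; triple-quoted strings, RDF collections and full JSON-LD 1.1
  container semantics are out of scope.
* **Dump partitioning.** Roots are typed subjects (optionally filtered by
  a root-class set); each root's sub-graph is everything reachable in at
  most 3 object-following hops — the bound prevents graph bleed between
  resources sharing a node.
* **Degenerate inputs.** Empty graphs fail F2B/I2/R1.3 rather than
  erroring; empty batches summarize to empty-but-headed exports; a
  profile without recommended properties has completeness 1 with a flag.
* **Problem sizes.** The test and acceptance suites use 1000 randomized
  ASK/oracle cases (graphs ≤ 50 triples), 50 randomized profiles for the
  shape-count law, exhaustive single-property removals on both fixture
  profiles, 500 random augmentations for monotonicity, and a 500-resource
  synthetic batch for recovery — sizes chosen so each law is exercised
  across its input space while a full run stays in the minutes range on
  one CPU.

## Known limitations

* Namespace-level vocabulary matching will call a misspelled term in a
  registered namespace "known"; term-level matching needs catalogs with
  explicit term lists.
* The R1.3 profile fallback depends on which profiles are configured;
  with none, domain-vocabulary usage is the only route.
* The SPARQL evaluator covers exactly the query shapes the package
  generates (VALUES-constrained ASK, bridge-property DESCRIBE); it is not
  a general SPARQL engine, and live-endpoint DESCRIBE responses are
  expected as N-Triples.
* Identifier-scheme detection is rule-based (DOI patterns and a short
  resolver-host list), not a registry lookup.
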