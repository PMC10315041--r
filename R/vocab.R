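# Vocabulary registry backends: which classes and properties does a graph
# use, and are they registered in a term catalog (general-purpose, like
# LOV, or life-science, like OLS/BioPortal)? The default backends are local
# fixture catalogs shipped with the package, so assessments are hermetic;
# live registry clients can be plugged in through the same interface.

#' Create a term catalog
#'
#' A catalog is a registry backend snapshot: a set of known term IRIs
#' and/or known namespace prefixes. Namespace-level matching is the
#' default; term-level matching applies when `known_terms` is provided.
#'
#' @param name Catalog name (unique within a configuration).
#' @param kind `"general"` (e.g. LOV-like) or `"domain"` (life-science,
#'   e.g. OLS/BioPortal-like).
#' @param known_terms Character vector of term IRIs.
#' @param known_namespaces Character vector of namespace IRIs.
#' @return A `term_catalog` object.
#' @export
term_catalog <- function(name, kind = c("general", "domain"),
                         known_terms = character(),
                         known_namespaces = character()) {
  kind <- match.arg(kind)
  known_terms <- expand_curie(known_terms)
  known_namespaces <- expand_curie(known_namespaces)
  if (length(known_terms)) {
    covered <- vapply(known_terms, function(t) {
      any(vapply(known_namespaces, function(ns) startsWith(t, ns), logical(1)))
    }, logical(1))
    if (!all(covered)) {
      abort(glue(
        "term_catalog '{name}': known term '{known_terms[!covered][1]}' ",
        "is not covered by any known namespace"
      ), class = "faircheckr_contract_error")
    }
  }
  structure(
    list(
      name = name, kind = kind,
      known_terms = known_terms, known_namespaces = known_namespaces
    ),
    class = "term_catalog"
  )
}

#' Read a term catalog from a plain-text file
#'
#' One IRI per line; lines ending in `/` or `#` are namespaces, other
#' lines are terms; `#`-prefixed lines are comments.
#'
#' @param path File path.
#' @param name Catalog name (defaults to the file stem).
#' @param kind `"general"` or `"domain"`.
#' @return A [term_catalog()].
#' @export
read_catalog <- function(path, name = NULL, kind = c("general", "domain")) {
  kind <- match.arg(kind)
  lines <- str_trim(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  is_ns <- str_detect(lines, "[/#]$")
  term_catalog(
    name = name %||% sub("\\.[^.]*$", "", basename(path)),
    kind = kind,
    known_terms = lines[!is_ns],
    known_namespaces = lines[is_ns]
  )
}

#' Default local catalog backends
#'
#' A general-vocabulary catalog (Schema.org, Dublin Core terms, DCAT,
#' PROV, PAV and the license vocabularies) and a life-science domain
#' catalog (EDAM and OBO namespaces), both read from files shipped with
#' the package.
#'
#' @return A list of [term_catalog()]s.
#' @export
default_catalogs <- function() {
  dir <- system.file("extdata", "catalogs", package = "faircheckr")
  list(
    read_catalog(file.path(dir, "general-vocab.txt"), name = "general-vocab", kind = "general"),
    read_catalog(file.path(dir, "lifescience-vocab.txt"), name = "lifescience-vocab", kind = "domain")
  )
}

#' Classes and properties used by a graph
#'
#' Properties are all predicates; classes are all IRI objects of
#' `rdf:type` (blank nodes and literals excluded).
#'
#' @param graph An [rdf_graph()].
#' @return A list with character vectors `classes` and `properties`.
#' @export
used_terms <- function(graph) {
  list(
    classes = sort(unique(graph$object[graph$predicate == RDF_TYPE &
      graph$object_kind == "iri"])),
    properties = sort(unique(graph$predicate))
  )
}

catalog_knows <- function(catalog, term) {
  if (term %in% catalog$known_terms) return(TRUE)
  any(vapply(catalog$known_namespaces, function(ns) startsWith(term, ns), logical(1)))
}

#' Look up a term across catalog backends
#'
#' @param term Term IRI (CURIEs with known prefixes accepted).
#' @param catalogs List of [term_catalog()]s.
#' @return A tibble with one row per catalog: `catalog`, `kind`, `known`.
#' @export
lookup_term <- function(term, catalogs = default_catalogs()) {
  term <- expand_curie(term)
  map_dfr(catalogs, function(cat) {
    known <- tryCatch(catalog_knows(cat, term), error = function(e) NA)
    tibble(catalog = cat$name, kind = cat$kind, known = known)
  })
}

# terms used by the graph, infrastructure vocabulary excluded
coverage_terms <- function(graph) {
  terms <- unique(c(used_terms(graph)$classes, used_terms(graph)$properties))
  infra <- infra_namespaces()
  terms[!vapply(terms, function(t) {
    any(vapply(infra, function(ns) startsWith(t, ns), logical(1)))
  }, logical(1))]
}

#' Fraction of used terms known to catalog backends, per backend kind
#'
#' @param graph An [rdf_graph()].
#' @param catalogs List of [term_catalog()]s.
#' @return A tibble with columns `kind`, `n_terms`, `n_known`, `coverage`,
#'   `empty` (flag set when the graph uses no countable terms; coverage is
#'   then 0).
#' @export
term_coverage <- function(graph, catalogs = default_catalogs()) {
  terms <- coverage_terms(graph)
  kinds <- unique(vapply(catalogs, function(c) c$kind, character(1)))
  map_dfr(kinds, function(k) {
    cats <- keep(catalogs, function(c) c$kind == k)
    known <- vapply(terms, function(t) {
      any(vapply(cats, catalog_knows, logical(1), term = t))
    }, logical(1))
    n <- length(terms)
    tibble(
      kind = k, n_terms = n, n_known = sum(known),
      coverage = if (n == 0) 0 else sum(known) / n,
      empty = n == 0
    )
  })
}
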