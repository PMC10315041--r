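# SPARQL query generation from templates, plus an evaluator for the
# generated ASK form. Each property-presence metric is materialized as an
# ASK query whose VALUES clause enumerates the metric's target properties;
# the query answers true when at least one target property occurs as a
# predicate in the assessed graph.

#' Generate a SPARQL ASK query over a target property set
#'
#' Instantiates the single ASK template used by every property-presence
#' metric: a `VALUES` clause binds the predicate variable to the target
#' properties, so the query answers true iff some triple's predicate is in
#' the list.
#'
#' @param target_properties Non-empty character vector of absolute property
#'   IRIs (CURIEs with known prefixes are expanded).
#' @return SPARQL ASK query text.
#' @examples
#' cat(build_values_ask(c("schema:license", "dct:license")))
#' @export
build_values_ask <- function(target_properties) {
  props <- expand_curie(target_properties)
  if (length(props) == 0) {
    abort("target_properties must be non-empty", class = "faircheckr_contract_error")
  }
  if (!all(is_absolute_iri(props))) {
    bad <- props[!is_absolute_iri(props)][1]
    abort(glue("target property is not an absolute IRI: '{bad}'"),
      class = "faircheckr_contract_error"
    )
  }
  paste0(
    "ASK {\n",
    "    VALUES ?p { ", paste0("<", props, ">", collapse = " "), " }\n",
    "    ?s ?p ?o .\n",
    "}\n"
  )
}

#' Evaluate a generated ASK query against a graph
#'
#' Evaluates queries of the form produced by [build_values_ask()]: the
#' VALUES-bound predicate list is read from the query text and tested
#' existentially against the graph's predicates.
#'
#' @param query ASK query text from [build_values_ask()].
#' @param graph An [rdf_graph()].
#' @return Logical scalar.
#' @export
ask <- function(query, graph) {
  props <- ask_query_properties(query)
  any(graph$predicate %in% props)
}

ask_query_properties <- function(query) {
  m <- str_match(query, regex("VALUES\\s+\\?p\\s*\\{([^}]*)\\}", ignore_case = TRUE))
  if (is.na(m[2])) {
    abort("Unsupported query form: expected an ASK with a VALUES ?p clause",
      class = "faircheckr_contract_error"
    )
  }
  iris <- str_match_all(m[2], "<([^>]*)>")[[1]][, 2]
  iris
}

#' @importFrom stringr str_match_all
NULL

# triples whose predicate is in the target list; evidence for metric results
matching_triples <- function(graph, target_properties) {
  props <- expand_curie(target_properties)
  as_rdf_graph(graph[graph$predicate %in% props, ])
}

#' Generate a SPARQL DESCRIBE query for knowledge-graph enrichment
#'
#' Builds the endpoint-specific DESCRIBE form that retrieves triples about
#' nodes cross-referenced to the resource's identifier through the
#' endpoint's bridge property (e.g. the DOI cross-reference property on
#' Wikidata). DOI-shaped identifiers are normalized (resolver host and
#' `doi:` prefix stripped, case-folded) before injection.
#'
#' @param resource_identifier Identifier string (URL, DOI, ...).
#' @param profile An [endpoint_profile()].
#' @return SPARQL DESCRIBE query text.
#' @export
build_describe <- function(resource_identifier, profile) {
  id <- resource_identifier
  if (profile$query_template_kind == "doi_crossref" || looks_like_doi(id)) {
    id <- normalize_doi(id)
  }
  id <- escape_literal(id)
  paste0(
    "DESCRIBE ?x WHERE {\n",
    "    ?x <", profile$bridge_property, "> \"", id, "\" .\n",
    "}\n"
  )
}

looks_like_doi <- function(x) {
  str_detect(tolower(x), "^(https?://(dx\\.)?doi\\.org/|doi:)?10\\.[0-9]{4,}/") ||
    str_detect(tolower(x), "^https?://(dx\\.)?doi\\.org/")
}

#' Normalize a DOI string
#'
#' Strips resolver hosts (`https://doi.org/`, `http://dx.doi.org/`) and the
#' `doi:` prefix, and lower-cases the result, yielding the bare
#' `10.xxxx/...` form injected into enrichment queries.
#'
#' @param x Character vector.
#' @return Character vector of bare lower-case DOIs (non-DOI input is
#'   lower-cased and returned otherwise unchanged).
#' @export
normalize_doi <- function(x) {
  out <- tolower(x)
  out <- str_replace(out, "^https?://(dx\\.)?doi\\.org/", "")
  str_replace(out, "^doi:", "")
}
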