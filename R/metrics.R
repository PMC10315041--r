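# The FAIR metrics engine. Twelve maturity indicators are evaluated per
# resource; property-presence metrics run through generated SPARQL ASK
# queries (one shared template, per-metric VALUES lists), the others test
# protocol, structure, registry or reference conditions. Alternative
# implementations of a metric can be registered and selected by name.

findability_properties <- function() {
  c("dct:identifier", "schema:identifier", "dct:title", "dct:description")
}

accessibility_properties <- function() {
  # curated accessibility list plus schema:downloadUrl
  c(
    "odrl:hasPolicy", "dct:rights", "dct:accessRights", "dcat:accessURL",
    "dcat:downloadURL", "dcat:endpointDescription", "dcat:endpointURL",
    "schema:downloadUrl"
  )
}

license_properties <- function() {
  c(
    "schema:license", "dct:license", "doap:license", "dbo:license",
    "cc:license", "xhv:license", "sto:license", "nie:license"
  )
}

provenance_properties <- function() {
  c(
    "prov:wasGeneratedBy", "prov:wasDerivedFrom", "prov:wasAttributedTo",
    "prov:used", "prov:wasInformedBy", "prov:wasAssociatedWith",
    "prov:startedAtTime", "prov:endedAtTime",
    "dct:hasVersion", "dct:isVersionOf", "dct:creator", "dct:contributor",
    "dct:publisher",
    "pav:hasVersion", "pav:version", "pav:hasCurrentVersion", "pav:createdBy",
    "pav:authoredBy", "pav:retrievedFrom", "pav:importedFrom",
    "pav:createdWith", "pav:retrievedBy", "pav:importedBy", "pav:curatedBy",
    "pav:createdAt", "pav:previousVersion",
    "schema:creator", "schema:author", "schema:publisher", "schema:provider",
    "schema:funder"
  )
}

#' The canonical FAIR metric definitions
#'
#' Twelve maturity indicators: globally unique identification (F1A),
#' persistent identification (F1B), structured metadata (F2A), shared
#' vocabularies (F2B), open retrieval protocol (A1.1), access policy
#' metadata (A1.2), formal knowledge-representation language (I1), FAIR
#' vocabularies (I2), qualified external references (I3), license (R1.1),
#' provenance (R1.2) and community standards (R1.3).
#'
#' @return A tibble with columns `metric_id`, `principle`, `priority`,
#'   `test_kind` and `target_properties` (list column of property IRIs;
#'   empty for non-property tests).
#' @export
metric_registry <- function() {
  if (!is.null(.metric_impls$.registry)) return(.metric_impls$.registry)
  .metric_impls$.registry <- build_metric_registry()
  .metric_impls$.registry
}

build_metric_registry <- function() {
  tibble(
    metric_id = METRIC_IDS,
    principle = c(
      "(Meta)data are assigned a globally unique identifier",
      "(Meta)data are assigned a persistent identifier",
      "Data are described with structured metadata",
      "Data are described with metadata populated using shared vocabularies",
      "(Meta)data are retrievable by their identifier using a standardised communication protocol: open, free, and universally implementable",
      "(Meta)data carry machine-readable access or usage policy information",
      "(Meta)data use a formal, accessible, shared, and broadly applicable language for knowledge representation",
      "(Meta)data use vocabularies that follow FAIR principles",
      "(Meta)data include qualified references to other (meta)data",
      "(Meta)data are released with a clear and accessible data usage license",
      "(Meta)data are associated with detailed provenance",
      "(Meta)data meet domain-relevant community standards"
    ),
    priority = c(
      "essential", "essential", "essential", "essential", "essential",
      "important", "important", "important", "useful", "essential",
      "important", "essential"
    ),
    test_kind = c(
      "structure", "property_presence", "structure", "registry", "protocol",
      "property_presence", "structure", "registry", "reference",
      "property_presence", "property_presence", "registry"
    ),
    target_properties = list(
      character(), expand_curie(findability_properties()), character(),
      character(), character(), expand_curie(accessibility_properties()),
      character(), character(), character(),
      expand_curie(license_properties()), expand_curie(provenance_properties()),
      character()
    )
  )
}

# ---- alternative implementation registry -----------------------------------

.metric_impls <- new.env(parent = emptyenv())

#' Register an alternative implementation for a metric
#'
#' Alternative implementations of the same metric are selectable by name
#' through `fair_config(implementations = c("R1.1" = "strict"))`; the
#' canonical implementation remains the default.
#'
#' @param metric_id One of the canonical metric ids.
#' @param name Implementation name (`"canonical"` is reserved).
#' @param fn Function `(resource, definition, config) -> metric result row`
#'   (see [evaluate_metric()]).
#' @return `fn`, invisibly.
#' @export
register_metric_impl <- function(metric_id, name, fn) {
  if (!metric_id %in% METRIC_IDS) {
    abort(glue("Unknown metric id '{metric_id}'"), class = "faircheckr_contract_error")
  }
  stopifnot(is.function(fn))
  key <- metric_id
  impls <- .metric_impls[[key]] %||% list()
  impls[[name]] <- fn
  .metric_impls[[key]] <- impls
  invisible(fn)
}

get_metric_impl <- function(metric_id, config) {
  sel <- config$implementations[[metric_id]] %||% "canonical"
  if (sel == "canonical") return(canonical_metric_impl)
  impl <- (.metric_impls[[metric_id]] %||% list())[[sel]]
  if (is.null(impl)) {
    abort(glue("No implementation '{sel}' registered for metric '{metric_id}'"),
      class = "faircheckr_contract_error"
    )
  }
  impl
}

# ---- result construction ---------------------------------------------------

metric_result_row <- function(metric_id, status, evidence = NULL, log = "") {
  evidence <- evidence %||% empty_graph()
  tibble(
    metric_id = metric_id,
    status = status,
    n_evidence = if (is.data.frame(evidence)) nrow(evidence) else length(evidence),
    evidence = list(evidence),
    recommendation = recommendation_for(metric_id, status)$text,
    log = log
  )
}

#' Test whether an identifier uses a persistent identification scheme
#'
#' Recognizes DOIs (bare `10.x/...` paths, `doi:` prefixes, doi.org
#' resolver hosts) and the identifiers.org, purl.* and w3id.org resolver
#' hosts; host matching is case-insensitive.
#'
#' @param identifier Identifier string.
#' @return Logical scalar (`FALSE` for unparseable input).
#' @export
check_identifier_scheme <- function(identifier) {
  if (is.na(identifier) || !nzchar(identifier)) return(FALSE)
  if (str_detect(identifier, "^(doi:)?10\\.[0-9]{4,}/")) return(TRUE)
  host <- uri_host(identifier)
  if (is.na(host)) return(FALSE)
  host %in% c("doi.org", "dx.doi.org", "identifiers.org", "w3id.org") ||
    startsWith(host, "purl.")
}

# ---- canonical implementations ---------------------------------------------

canonical_metric_impl <- function(resource, definition, config) {
  fn <- switch(definition$metric_id,
    "F1A" = metric_f1a, "F1B" = metric_f1b, "F2A" = metric_f2a,
    "F2B" = metric_f2b, "A1.1" = metric_a11, "A1.2" = metric_property,
    "I1" = metric_i1, "I2" = metric_i2, "I3" = metric_i3,
    "R1.1" = metric_property, "R1.2" = metric_property, "R1.3" = metric_r13
  )
  fn(resource, definition, config)
}

#' Evaluate one metric on an annotated resource
#'
#' @param resource An `annotated_resource` (see [make_resource()]).
#' @param definition One row of [metric_registry()] (or a compatible
#'   one-row data frame).
#' @param config A [fair_config()].
#' @return A one-row tibble: `metric_id`, `status` (`"pass"`, `"fail"` or
#'   `"error"`), `n_evidence`, `evidence` (list column), `recommendation`,
#'   `log`.
#' @export
evaluate_metric <- function(resource, definition, config = fair_config()) {
  definition <- as.list(definition)
  if (is.list(definition$target_properties) &&
        length(definition$target_properties) == 1 &&
        is.character(definition$target_properties[[1]])) {
    definition$target_properties <- definition$target_properties[[1]]
  }
  impl <- get_metric_impl(definition$metric_id, config)
  tryCatch(
    impl(resource, definition, config),
    error = function(e) {
      metric_result_row(definition$metric_id, "error",
        log = paste("infrastructure error:", conditionMessage(e))
      )
    }
  )
}

# property-presence semantics: generated ASK query over the target list
metric_property <- function(resource, definition, config) {
  query <- build_values_ask(definition$target_properties)
  hit <- ask(query, resource$graph)
  evidence <- matching_triples(resource$graph, definition$target_properties)
  metric_result_row(
    definition$metric_id,
    if (hit) "pass" else "fail",
    evidence = evidence,
    log = if (isTRUE(config$show_queries)) query else ""
  )
}

metric_f1a <- function(resource, definition, config) {
  ok <- is_absolute_iri(resource$subject_url)
  metric_result_row(
    "F1A", if (ok) "pass" else "fail",
    evidence = if (ok) list(subject_url = resource$subject_url) else NULL,
    log = glue("subject '{resource$subject_url}' absolute URI: {ok}")
  )
}

# persistent identifier: identifier property present OR the subject URL
# itself uses a persistent scheme (disjunction; both routes recorded)
metric_f1b <- function(resource, definition, config) {
  evidence <- matching_triples(resource$graph, definition$target_properties)
  scheme_ok <- check_identifier_scheme(resource$subject_url)
  pass <- nrow(evidence) > 0 || scheme_ok
  metric_result_row(
    "F1B", if (pass) "pass" else "fail",
    evidence = evidence,
    log = glue(
      "identifier properties: {nrow(evidence)}; ",
      "persistent scheme on subject URL: {scheme_ok}"
    )
  )
}

metric_f2a <- function(resource, definition, config) {
  n <- n_triples(resource$graph)
  metric_result_row(
    "F2A", if (n > 0) "pass" else "fail",
    evidence = resource$graph,
    log = glue("{n} harvested triple(s)")
  )
}

metric_f2b <- function(resource, definition, config) {
  terms <- coverage_terms(resource$graph)
  known <- terms[vapply(terms, function(t) {
    any(map_lgl(config$catalogs, catalog_knows, term = t))
  }, logical(1))]
  metric_result_row(
    "F2B", if (length(known) > 0) "pass" else "fail",
    evidence = known,
    log = glue("{length(known)} of {length(terms)} used term(s) known to a registry")
  )
}

metric_a11 <- function(resource, definition, config) {
  scheme <- uri_scheme(resource$subject_url)
  open_protocol <- !is.na(scheme) && scheme %in% c("http", "https", "ftp")
  resolved <- if (resource$content_kind == "rdf_serialization") {
    TRUE # dump content was retrieved and parsed
  } else {
    !is.na(resource$http_status) && resource$http_status < 400
  }
  pass <- open_protocol && resolved
  metric_result_row(
    "A1.1", if (pass) "pass" else "fail",
    evidence = if (pass) list(scheme = scheme, status = resource$http_status) else NULL,
    log = glue("scheme={scheme %||% NA}; resolved={resolved}")
  )
}

metric_i1 <- function(resource, definition, config) {
  from_rdf <- n_triples(resource$graph) > 0 &&
    (length(resource$syntaxes_found) > 0 ||
       resource$content_kind == "rdf_serialization")
  metric_result_row(
    "I1", if (from_rdf) "pass" else "fail",
    evidence = resource$graph,
    log = glue("syntaxes: {paste(resource$syntaxes_found, collapse = ', ')}")
  )
}

metric_i2 <- function(resource, definition, config) {
  if (n_triples(resource$graph) == 0) {
    return(metric_result_row("I2", "fail", log = "empty graph"))
  }
  terms <- coverage_terms(resource$graph)
  ns <- unique(iri_namespace(terms))
  ns <- ns[!is.na(ns)]
  known <- vapply(ns, function(n) {
    any(map_lgl(config$catalogs, catalog_knows, term = n))
  }, logical(1))
  pass <- all(known)
  metric_result_row(
    "I2", if (pass) "pass" else "fail",
    evidence = ns[known],
    log = if (pass) "all used namespaces registered" else {
      glue("unregistered namespace(s): {paste(ns[!known], collapse = ', ')}")
    }
  )
}

metric_i3 <- function(resource, definition, config) {
  subj_auth <- uri_authority(resource$subject_url)
  g <- resource$graph
  cand <- g[g$predicate != RDF_TYPE & g$object_kind == "iri", ]
  if (nrow(cand)) {
    auths <- uri_authority(cand$object)
    external <- is.na(auths) | is.na(subj_auth) | auths != subj_auth
    cand <- cand[external & !is.na(cand$object), ]
  }
  metric_result_row(
    "I3", if (nrow(cand) > 0) "pass" else "fail",
    evidence = as_rdf_graph(cand),
    log = glue("{nrow(cand)} qualified external reference(s)")
  )
}

metric_r13 <- function(resource, definition, config) {
  terms <- coverage_terms(resource$graph)
  domain_cats <- keep(config$catalogs, function(c) c$kind == "domain")
  known <- terms[vapply(terms, function(t) {
    any(map_lgl(domain_cats, catalog_knows, term = t))
  }, logical(1))]
  if (length(known) > 0) {
    return(metric_result_row("R1.3", "pass",
      evidence = known,
      log = "domain-registry term(s) in use"
    ))
  }
  # fall back to community-profile conformance
  entity <- primary_entity(resource)
  if (!is.na(entity) && length(config$profiles) > 0) {
    prof <- select_profile(resource$graph, entity, config$profiles)
    if (!is.null(prof)) {
      report <- validate_shape(resource$graph, generate_shape(prof), focus = entity)
      if (attr(report, "conforms")) {
        return(metric_result_row("R1.3", "pass",
          evidence = list(profile = prof$name),
          log = glue("conforms to community profile '{prof$name}'")
        ))
      }
      return(metric_result_row("R1.3", "fail",
        log = glue("profile '{prof$name}' matched with violations; no domain terms")
      ))
    }
  }
  metric_result_row("R1.3", "fail", log = "no domain-registry terms, no applicable profile")
}

# the entity a profile check focuses on: the subject URL when it occurs as
# a subject, else the first typed subject (stable order)
primary_entity <- function(resource) {
  g <- resource$graph
  if (resource$subject_url %in% g$subject) return(resource$subject_url)
  typed <- sort(unique(g$subject[g$predicate == RDF_TYPE]))
  if (length(typed)) typed[1] else NA_character_
}

#' Evaluate all twelve FAIR metrics on a resource
#'
#' Results are emitted in canonical metric order (F1A ... R1.3). When
#' enrichment is enabled in the configuration it runs before evaluation,
#' so enriched triples count as metric evidence. A failure inside one
#' metric yields an `"error"` status for that metric only.
#'
#' @param resource An `annotated_resource`.
#' @param config A [fair_config()].
#' @return A `fair_result` tibble with one row per metric.
#' @export
evaluate_all <- function(resource, config = fair_config()) {
  if (isTRUE(config$enrichment)) {
    resource <- enrich(resource, profiles = config$endpoints,
                       transport = config$transport)
  }
  defs <- metric_registry()
  rows <- map(seq_len(nrow(defs)), function(i) {
    evaluate_metric(resource, defs[i, ], config)
  })
  out <- bind_rows(rows)
  out <- left_join(out, defs[, c("metric_id", "priority", "test_kind")], by = "metric_id")
  out <- out[match(METRIC_IDS, out$metric_id), ]
  attr(out, "subject_url") <- resource$subject_url
  class(out) <- c("fair_result", class(tibble()))
  out
}

#' Package-level configuration for an assessment run
#'
#' @param offline Forbid live transports and registries (default `TRUE`).
#' @param enrichment Run knowledge-graph enrichment before metric
#'   evaluation (default `FALSE`).
#' @param endpoints List of [endpoint_profile()]s used for enrichment.
#' @param transport Transport function `(endpoint_profile, query) ->
#'   rdf_graph` (e.g. [fixture_transport()]); `NULL` disables enrichment
#'   retrieval.
#' @param catalogs Vocabulary registry backends ([term_catalog()] list).
#' @param profiles Community profiles ([profile_spec()] list) available
#'   for selection.
#' @param implementations Named character vector selecting alternative
#'   metric implementations by metric id.
#' @param renderer Optional client-side rendering function for [fetch()].
#' @param show_queries Include generated SPARQL text in metric logs.
#' @param cache_ttl_resource Resource-metadata cache TTL in seconds
#'   (default 60).
#' @param cache_ttl_registry Registry-answer cache TTL in seconds
#'   (default 14 days).
#' @return A `fair_config` list.
#' @export
fair_config <- function(offline = TRUE, enrichment = FALSE,
                        endpoints = default_endpoints(), transport = NULL,
                        catalogs = default_catalogs(),
                        profiles = default_profiles(),
                        implementations = character(),
                        renderer = NULL, show_queries = FALSE,
                        cache_ttl_resource = 60,
                        cache_ttl_registry = 14 * 24 * 3600) {
  if (offline && !is.null(transport) && isTRUE(attr(transport, "live"))) {
    abort("offline configuration forbids live transports",
      class = "faircheckr_contract_error"
    )
  }
  structure(
    list(
      offline = offline, enrichment = enrichment, endpoints = endpoints,
      transport = transport, catalogs = catalogs, profiles = profiles,
      implementations = as.list(implementations), renderer = renderer,
      show_queries = show_queries,
      cache_ttl_resource = cache_ttl_resource,
      cache_ttl_registry = cache_ttl_registry
    ),
    class = "fair_config"
  )
}

#' @export
print.fair_result <- function(x, ...) {
  cat("# FAIR assessment:", sum(x$status == "pass"), "of", nrow(x), "metrics passed\n")
  NextMethod()
}
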