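# Knowledge-graph enrichment: DESCRIBE queries generated per endpoint
# profile retrieve triples cross-referenced to the resource's identifier
# (typically a DOI). Transports are pluggable: a live SPARQL-protocol
# client or a fixture transport reading canned result graphs, plus a
# TTL cache decorator. Default operation is offline with fixture
# transports; live endpoints are opt-in.

#' Describe a public knowledge-graph endpoint
#'
#' @param name Unique endpoint name.
#' @param endpoint_url SPARQL endpoint URL.
#' @param bridge_property IRI of the cross-reference predicate linking
#'   endpoint nodes to the resource identifier.
#' @param query_template_kind One of `"doi_crossref"`, `"persistent_id"`,
#'   `"identifier"`.
#' @return An `endpoint_profile` object.
#' @export
endpoint_profile <- function(name, endpoint_url, bridge_property,
                             query_template_kind = c("doi_crossref", "persistent_id", "identifier")) {
  query_template_kind <- match.arg(query_template_kind)
  structure(
    list(
      name = name, endpoint_url = endpoint_url,
      bridge_property = expand_curie(bridge_property),
      query_template_kind = query_template_kind
    ),
    class = "endpoint_profile"
  )
}

#' Default public knowledge-graph endpoint profiles
#'
#' Wikidata (DOI cross-reference property P356), OpenAIRE (persistent
#' resource identifier) and OpenCitations (DataCite identifier bridge).
#'
#' @return A named list of [endpoint_profile()]s.
#' @export
default_endpoints <- function() {
  list(
    wikidata = endpoint_profile(
      "wikidata", "https://query.wikidata.org/sparql",
      "http://www.wikidata.org/prop/direct/P356", "doi_crossref"
    ),
    openaire = endpoint_profile(
      "openaire", "https://lod.openaire.eu/sparql",
      "http://lod.openaire.eu/vocab#resPersistentID", "persistent_id"
    ),
    opencitations = endpoint_profile(
      "opencitations", "https://opencitations.net/sparql",
      "http://purl.org/spar/datacite/hasIdentifier", "identifier"
    )
  )
}

#' Enrich a resource's graph from knowledge-graph endpoints
#'
#' For each endpoint profile a DESCRIBE query is generated from the
#' resource's identifiers and executed through `transport`; retrieved
#' triples are unioned into the graph. Original triples are never removed;
#' a failing endpoint is logged and skipped.
#'
#' @param resource An `annotated_resource`.
#' @param profiles List of [endpoint_profile()]s.
#' @param transport Function `(endpoint_profile, query) -> rdf_graph`
#'   (e.g. [fixture_transport()]); `NULL` leaves the resource unchanged.
#' @return The enriched `annotated_resource`.
#' @export
enrich <- function(resource, profiles = default_endpoints(), transport = NULL) {
  if (is.null(transport)) return(resource)
  ids <- resource_identifiers(resource)
  for (profile in profiles) {
    for (id in ids) {
      query <- build_describe(id, profile)
      g <- tryCatch(
        transport(profile, query),
        error = function(e) {
          warn(glue("Enrichment via '{profile$name}' failed: {conditionMessage(e)}; skipping"))
          NULL
        }
      )
      if (!is.null(g) && n_triples(g) > 0) {
        resource$graph <- graph_union(resource$graph, g)
      }
    }
  }
  resource
}

# identifiers worth cross-referencing: the subject URL plus any
# identifier-property values (literal or IRI)
resource_identifiers <- function(resource) {
  ids <- resource$subject_url
  idg <- matching_triples(resource$graph, findability_properties())
  unique(c(ids, idg$object))
}

#' Fixture transport reading canned result graphs from a directory
#'
#' Results are Turtle files named by the SHA-1 digest of the exact query
#' text (`<digest>.ttl`); a missing file yields the empty graph. This
#' makes offline enrichment fully deterministic.
#'
#' @param dir Directory of canned `.ttl` files.
#' @return A transport function for [enrich()].
#' @export
fixture_transport <- function(dir) {
  force(dir)
  f <- function(profile, query) {
    path <- file.path(dir, paste0(digest::digest(query, algo = "sha1", serialize = FALSE), ".ttl"))
    if (!file.exists(path)) return(empty_graph())
    read_rdf(path, "turtle")
  }
  attr(f, "live") <- FALSE
  f
}

#' Write a canned fixture response for a query
#'
#' Companion to [fixture_transport()]: stores `graph` so that the given
#' query text returns it.
#'
#' @param dir Fixture directory.
#' @param query Exact query text.
#' @param graph The [rdf_graph()] to return.
#' @return The file path, invisibly.
#' @export
write_fixture_response <- function(dir, query, graph) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(digest::digest(query, algo = "sha1", serialize = FALSE), ".ttl"))
  write_turtle(graph, path)
  invisible(path)
}

#' Live SPARQL-protocol transport
#'
#' Executes queries over HTTP against each endpoint's URL, expecting an
#' N-Triples response to the DESCRIBE. Opt-in: offline configurations
#' reject it.
#'
#' @param timeout Timeout in seconds.
#' @return A transport function for [enrich()].
#' @export
live_transport <- function(timeout = 30) {
  f <- function(profile, query) {
    h <- curl::new_handle(
      timeout = timeout, useragent = FAIR_USER_AGENT,
      httpheader = c(Accept = "application/n-triples, text/plain")
    )
    url <- paste0(profile$endpoint_url, "?query=", curl::curl_escape(query))
    resp <- curl::curl_fetch_memory(url, handle = h)
    if (resp$status_code >= 400) {
      abort(glue("endpoint '{profile$name}' returned status {resp$status_code}"))
    }
    parse_ntriples(rawToChar(resp$content))
  }
  attr(f, "live") <- TRUE
  f
}

#' Decorate a transport with a time-to-live cache
#'
#' Identical (endpoint, query-text) pairs within the TTL are served from
#' the cache without calling the underlying transport.
#'
#' @param transport A transport function.
#' @param ttl Time to live in seconds (> 0).
#' @return A caching transport function; the attached environment exposes
#'   `calls`, the number of underlying transport invocations.
#' @export
cached <- function(transport, ttl) {
  if (!is.numeric(ttl) || ttl <= 0) {
    abort("ttl must be > 0", class = "faircheckr_contract_error")
  }
  store <- new.env(parent = emptyenv())
  store$calls <- 0L
  f <- function(profile, query) {
    key <- paste0(profile$endpoint_url, "\n", query)
    hit <- store[[key]]
    now <- as.numeric(Sys.time())
    if (!is.null(hit) && now - hit$at < ttl) return(hit$graph)
    store$calls <- store$calls + 1L
    g <- transport(profile, query)
    store[[key]] <- list(graph = g, at = now)
    g
  }
  attr(f, "live") <- isTRUE(attr(transport, "live"))
  attr(f, "store") <- store
  f
}
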