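# Tibble-backed RDF graph. A graph is a set of triples; each row is one
# triple. Object terms carry a kind (iri / blank / literal) plus optional
# language tag or datatype for literals. Blank nodes are written "_:label".

#' Create an RDF graph
#'
#' An `rdf_graph` is a tibble with one row per triple and columns
#' `subject`, `predicate`, `object`, `object_kind` (`"iri"`, `"blank"` or
#' `"literal"`), `lang` and `datatype`. Set semantics are enforced:
#' duplicate triples are dropped on construction and on union.
#'
#' @param subject,predicate,object Character vectors (recycled to common
#'   length). CURIEs with known prefixes are expanded. Blank nodes are
#'   written `"_:label"`.
#' @param object_kind Optional character vector; if `NULL` it is inferred
#'   (absolute IRI or `_:` prefix versus literal).
#' @param lang,datatype Optional literal language tags / datatype IRIs.
#' @return An `rdf_graph` tibble.
#' @examples
#' g <- rdf_graph("https://example.org/x", "schema:name", "PhyML")
#' @export
rdf_graph <- function(subject = character(), predicate = character(),
                      object = character(), object_kind = NULL,
                      lang = NA_character_, datatype = NA_character_) {
  n <- max(length(subject), length(predicate), length(object), 0L)
  if (n == 0L) return(empty_graph())
  subject <- expand_curie(rep_len(as.character(subject), n))
  predicate <- expand_curie(rep_len(as.character(predicate), n))
  object <- rep_len(as.character(object), n)
  if (is.null(object_kind)) {
    expanded <- expand_curie(object)
    is_curie_iri <- expanded != object # a known CURIE was expanded
    object <- expanded
    object_kind <- dplyr::case_when(
      startsWith(object, "_:") ~ "blank",
      is_curie_iri | is_absolute_iri(object) ~ "iri",
      TRUE ~ "literal"
    )
  } else {
    object_kind <- rep_len(object_kind, n)
    object[object_kind == "iri"] <- expand_curie(object[object_kind == "iri"])
  }
  g <- tibble(
    subject = subject, predicate = predicate, object = object,
    object_kind = object_kind,
    lang = rep_len(as.character(lang), n),
    datatype = expand_curie(rep_len(as.character(datatype), n))
  )
  as_rdf_graph(g)
}

graph_cols <- c("subject", "predicate", "object", "object_kind", "lang", "datatype")

#' The empty RDF graph
#' @return An [rdf_graph()] with zero triples.
#' @export
empty_graph <- function() {
  as_rdf_graph(tibble(
    subject = character(), predicate = character(), object = character(),
    object_kind = character(), lang = character(), datatype = character()
  ))
}

#' Coerce a data frame of triples to an `rdf_graph`
#'
#' Missing columns are filled (`object_kind` inferred, `lang`/`datatype`
#' set to `NA`); duplicate triples are removed.
#'
#' @param x A data frame with at least `subject`, `predicate`, `object`.
#' @return An `rdf_graph` tibble.
#' @export
as_rdf_graph <- function(x) {
  stopifnot(all(c("subject", "predicate", "object") %in% names(x)))
  x <- as_tibble(x)
  if (!"object_kind" %in% names(x)) {
    x$object_kind <- ifelse(startsWith(x$object, "_:"), "blank",
      ifelse(is_absolute_iri(x$object), "iri", "literal")
    )
  }
  if (!"lang" %in% names(x)) x$lang <- NA_character_
  if (!"datatype" %in% names(x)) x$datatype <- NA_character_
  x <- distinct(x[, graph_cols])
  # zero-row vector operations can demote columns to logical; keep chr
  x[graph_cols] <- lapply(x[graph_cols], as.character)
  class(x) <- c("rdf_graph", class(tibble()))
  x
}

#' Set union of RDF graphs
#'
#' @param ... `rdf_graph` objects (or coercible data frames).
#' @return The deduplicated union as an `rdf_graph`.
#' @export
graph_union <- function(...) {
  gs <- compact(list(...))
  if (length(gs) == 0) return(empty_graph())
  as_rdf_graph(bind_rows(lapply(gs, as_rdf_graph)))
}

#' Number of triples in a graph
#' @param graph An `rdf_graph`.
#' @return Integer count.
#' @export
n_triples <- function(graph) nrow(graph)

#' @export
print.rdf_graph <- function(x, ...) {
  cat("# RDF graph:", nrow(x), "triple(s)\n")
  NextMethod()
}

# stable total order on triples, used by serializers for reproducible output
sort_graph <- function(graph) {
  arrange(as_rdf_graph(graph), .data$subject, .data$predicate,
          .data$object_kind, .data$object, .data$lang, .data$datatype)
}

# deterministic blank-node factory; `prefix` keeps blank scopes apart
# (e.g. per embedded-annotation block, so distinct blocks never smush)
blank_factory <- function(prefix = "b") {
  i <- 0L
  function() {
    i <<- i + 1L
    paste0("_:", prefix, i)
  }
}
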