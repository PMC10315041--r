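# IRI handling: scheme/authority parsing, relative-reference resolution,
# CURIE expansion against the built-in prefix table.

#' Well-known namespace prefixes
#'
#' Prefix-to-IRI table used for CURIE expansion and compaction throughout the
#' package (generated queries, shapes, human-readable messages).
#'
#' @return A named character vector mapping prefix to namespace IRI.
#' @export
fair_namespaces <- function() {
  c(
    rdf    = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs   = "http://www.w3.org/2000/01/rdf-schema#",
    owl    = "http://www.w3.org/2002/07/owl#",
    xsd    = "http://www.w3.org/2001/XMLSchema#",
    sh     = "http://www.w3.org/ns/shacl#",
    schema = "https://schema.org/",
    dct    = "http://purl.org/dc/terms/",
    dcat   = "http://www.w3.org/ns/dcat#",
    prov   = "http://www.w3.org/ns/prov#",
    pav    = "http://purl.org/pav/",
    doap   = "http://usefulinc.com/ns/doap#",
    dbo    = "http://dbpedia.org/ontology/",
    cc     = "http://creativecommons.org/ns#",
    xhv    = "http://www.w3.org/1999/xhtml/vocab#",
    sto    = "https://w3id.org/i40/sto#",
    nie    = "http://www.semanticdesktop.org/ontologies/2007/01/19/nie#",
    odrl   = "http://www.w3.org/ns/odrl/2/",
    edam   = "http://edamontology.org/",
    wdt    = "http://www.wikidata.org/prop/direct/",
    openaire = "http://lod.openaire.eu/vocab#",
    datacite = "http://purl.org/spar/datacite/"
  )
}

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

# namespaces treated as serialization infrastructure, not domain vocabulary
infra_namespaces <- function() {
  unname(fair_namespaces()[c("rdf", "rdfs", "owl", "xsd")])
}

#' Expand a compact IRI (CURIE) against the built-in prefix table
#'
#' Strings that are already absolute IRIs (or whose prefix is unknown) are
#' returned unchanged, so the function is safe to apply to mixed input.
#'
#' @param x Character vector of CURIEs or IRIs.
#' @return Character vector of IRIs.
#' @examples
#' expand_curie("schema:license")
#' @export
expand_curie <- function(x) {
  ns <- fair_namespaces()
  m <- str_match(x, "^([A-Za-z][A-Za-z0-9._-]*):(.*)$")
  ifelse(!is.na(m[, 2]) & m[, 2] %in% names(ns),
    paste0(unname(ns[m[, 2]]), m[, 3]), x
  )
}

#' Compact an IRI to prefixed form where a known namespace matches
#'
#' @param x Character vector of IRIs.
#' @return Character vector; entries under a known namespace become
#'   `prefix:local`, others are returned unchanged.
#' @export
compact_iri <- function(x) {
  ns <- fair_namespaces()
  out <- x
  for (p in names(ns)) {
    hit <- !is.na(out) & startsWith(out, ns[[p]]) & out == x
    out[hit] <- paste0(p, ":", substr(x[hit], nchar(ns[[p]]) + 1L, nchar(x[hit])))
  }
  out
}

#' Test whether strings are syntactically absolute IRIs
#'
#' An absolute IRI has a scheme (`scheme:...` per RFC 3986) and no
#' whitespace or angle brackets.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_absolute_iri <- function(x) {
  !is.na(x) &
    str_detect(x, "^[A-Za-z][A-Za-z0-9+.-]*:\\S*$") &
    !str_detect(x, "[<>\"{}|\\\\^`\\s]")
}

uri_scheme <- function(x) {
  tolower(str_match(x, "^([A-Za-z][A-Za-z0-9+.-]*):")[, 2])
}

uri_authority <- function(x) {
  tolower(str_match(x, "^[A-Za-z][A-Za-z0-9+.-]*://([^/?#]*)")[, 2])
}

uri_host <- function(x) {
  auth <- uri_authority(x)
  # strip userinfo and port
  host <- str_replace(auth, "^.*@", "")
  str_replace(host, ":[0-9]*$", "")
}

strip_fragment <- function(x) str_replace(x, "#.*$", "")

#' Resolve a (possibly relative) IRI reference against a base IRI
#'
#' Implements the common cases of RFC 3986 reference resolution: absolute
#' references, network-path (`//`), absolute-path (`/`), fragment-only and
#' relative-path references with `.`/`..` segment removal.
#'
#' @param ref Character vector of references.
#' @param base Single base IRI (absolute) or `NA` to leave references as-is.
#' @return Character vector of resolved IRIs.
#' @export
resolve_iri <- function(ref, base) {
  if (is.null(base) || is.na(base) || !is_absolute_iri(base)) {
    return(ref)
  }
  vapply(ref, function(r) resolve_one(r, base), character(1), USE.NAMES = FALSE)
}

resolve_one <- function(r, base) {
  if (is.na(r)) return(NA_character_)
  if (is_absolute_iri(r)) return(r)
  scheme <- uri_scheme(base)
  auth <- uri_authority(base)
  if (r == "") return(strip_fragment(base))
  if (startsWith(r, "//")) return(paste0(scheme, ":", r))
  if (startsWith(r, "#")) return(paste0(strip_fragment(base), r))
  if (startsWith(r, "?")) {
    return(paste0(str_replace(strip_fragment(base), "\\?.*$", ""), r))
  }
  root <- if (!is.na(auth)) paste0(scheme, "://", auth) else paste0(scheme, ":")
  base_path <- str_replace(strip_fragment(base), "^[A-Za-z][A-Za-z0-9+.-]*:(//[^/?#]*)?", "")
  base_path <- str_replace(base_path, "\\?.*$", "")
  path <- if (startsWith(r, "/")) r else {
    dir <- str_replace(base_path, "[^/]*$", "")
    paste0(if (dir == "") "/" else dir, r)
  }
  paste0(root, remove_dot_segments(path))
}

remove_dot_segments <- function(path) {
  out <- character()
  for (seg in str_split(path, "/")[[1]]) {
    if (seg == ".") next
    if (seg == "..") {
      if (length(out) > 1) out <- out[-length(out)]
    } else {
      out <- c(out, seg)
    }
  }
  # preserve trailing slash semantics of "." / ".."
  last <- str_match(path, "/(\\.|\\.\\.)$")[, 2]
  res <- paste(out, collapse = "/")
  if (!is.na(last) && !endsWith(res, "/")) res <- paste0(res, "/")
  res
}

#' Namespace of an IRI
#'
#' The namespace is the IRI up to and including the last `#` or, failing
#' that, the last `/`.
#'
#' @param x Character vector of IRIs.
#' @return Character vector of namespace IRIs (`NA` where none found).
#' @export
iri_namespace <- function(x) {
  ns <- str_match(x, "^(.*#)")[, 2]
  slash <- str_match(x, "^(.*/)")[, 2]
  out <- ifelse(!is.na(ns), ns, slash)
  out
}
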