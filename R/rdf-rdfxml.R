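# RDF/XML subset reader built on xml2: node elements (rdf:Description or
# typed), rdf:about / rdf:nodeID / rdf:ID subjects, property elements with
# rdf:resource, rdf:nodeID, nested node elements or literal content
# (xml:lang, rdf:datatype). Property attributes and rdf:parseType are not
# supported.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

#' Parse RDF/XML text into triples
#'
#' @param x RDF/XML content as a string.
#' @param base Optional base IRI.
#' @return An `rdf_graph`.
#' @export
parse_rdfxml <- function(x, base = NA_character_) {
  doc <- xml2::read_xml(paste(x, collapse = "\n"))
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$bnode <- blank_factory("x")
  emit <- function(s, p, o, kind, lang = NA_character_, dt = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <- list(
      subject = s, predicate = p, object = o,
      object_kind = kind, lang = lang, datatype = dt
    )
  }
  el_iri <- function(el) {
    # expand the element's qualified name to an IRI using its namespace
    ns <- xml2::xml_ns(doc)
    qn <- xml2::xml_name(el, ns = ns)
    parts <- str_match(qn, "^(?:([^:]+):)?(.*)$")
    pfx <- parts[2]
    local <- parts[3]
    if (!is.na(pfx) && pfx %in% names(ns)) paste0(ns[[pfx]], local) else local
  }
  rdf_attr <- function(el, name) {
    v <- xml2::xml_attr(el, paste0("rdf:", name))
    if (is.na(v)) xml2::xml_attr(el, name) else v
  }

  node_element <- function(el) {
    about <- rdf_attr(el, "about")
    node_id <- rdf_attr(el, "nodeID")
    rid <- rdf_attr(el, "ID")
    subj <- if (!is.na(about)) {
      resolve_iri(about, base)
    } else if (!is.na(node_id)) {
      paste0("_:", node_id)
    } else if (!is.na(rid)) {
      resolve_iri(paste0("#", rid), base)
    } else {
      st$bnode()
    }
    kind <- if (startsWith(subj, "_:")) "blank" else "iri"
    type_iri <- el_iri(el)
    if (type_iri != paste0(RDF_NS, "Description")) {
      emit(subj, RDF_TYPE, type_iri, "iri")
    }
    for (prop in xml2::xml_children(el)) {
      pred <- el_iri(prop)
      res <- rdf_attr(prop, "resource")
      pnid <- rdf_attr(prop, "nodeID")
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        emit(subj, pred, resolve_iri(res, base), "iri")
      } else if (!is.na(pnid)) {
        emit(subj, pred, paste0("_:", pnid), "blank")
      } else if (length(kids) > 0) {
        child <- node_element(kids[[1]])
        emit(subj, pred, child, if (startsWith(child, "_:")) "blank" else "iri")
      } else {
        dt <- rdf_attr(prop, "datatype")
        lang <- xml2::xml_attr(prop, "xml:lang")
        emit(subj, pred, xml2::xml_text(prop), "literal",
          if (is.na(lang)) NA_character_ else lang,
          if (is.na(dt)) NA_character_ else dt
        )
      }
    }
    subj
  }

  root <- xml2::xml_root(doc)
  nodes <- if (el_iri(root) == paste0(RDF_NS, "RDF")) xml2::xml_children(root) else list(root)
  for (el in nodes) node_element(el)
  if (length(st$rows) == 0) return(empty_graph())
  as_rdf_graph(bind_rows(lapply(st$rows, as_tibble)))
}
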