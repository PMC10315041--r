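# Embedded-annotation extraction: JSON-LD script blocks, RDFa attributes
# and HTML microdata, merged into one deduplicated graph. Blank-node labels
# are scoped per annotation block so nodes from distinct blocks are never
# merged. schema.org IRIs are normalized to the https:// form so pages
# using either variant evaluate identically.

normalize_schema_iris <- function(graph) {
  if (nrow(graph) == 0) return(as_rdf_graph(graph))
  fix <- function(x) str_replace(x, "^http://schema\\.org/", "https://schema.org/")
  graph %>%
    mutate(
      subject = fix(.data$subject),
      predicate = fix(.data$predicate),
      object = ifelse(.data$object_kind == "iri", fix(.data$object), .data$object)
    ) %>%
    as_rdf_graph()
}

#' Extract all embedded structured annotations from an HTML document
#'
#' Parses the document tolerantly and merges triples found in JSON-LD
#' `<script>` blocks, RDFa attributes and HTML microdata. A malformed
#' JSON-LD block is skipped with a warning; it never aborts extraction of
#' the remaining blocks.
#'
#' @param document HTML text.
#' @param base_url Absolute IRI used to resolve relative references; the
#'   document's own `<base href>` takes precedence when present.
#' @return A list with elements `graph` (an [rdf_graph()]) and
#'   `syntaxes_found` (character subset of `c("json-ld", "rdfa",
#'   "microdata")`).
#' @export
extract_embedded <- function(document, base_url = NA_character_) {
  doc <- xml2::read_html(paste(document, collapse = "\n"))
  declared_base <- xml2::xml_attr(xml2::xml_find_first(doc, "//base"), "href")
  base <- if (!is.na(declared_base)) declared_base else base_url

  syntaxes <- character()
  graphs <- list()

  # JSON-LD
  scripts <- xml2::xml_find_all(
    doc, "//script[@type='application/ld+json']"
  )
  jsonld <- empty_graph()
  for (i in seq_along(scripts)) {
    g <- tryCatch(
      parse_jsonld(xml2::xml_text(scripts[[i]]), base = base,
                   bnode_prefix = paste0("j", i, "_")),
      error = function(e) {
        warn(glue("Skipping malformed JSON-LD block {i}: {conditionMessage(e)}"))
        NULL
      }
    )
    if (!is.null(g)) jsonld <- graph_union(jsonld, g)
  }
  if (n_triples(jsonld) > 0) {
    syntaxes <- c(syntaxes, "json-ld")
    graphs <- c(graphs, list(jsonld))
  }

  rdfa <- extract_rdfa(doc, base)
  if (n_triples(rdfa) > 0) {
    syntaxes <- c(syntaxes, "rdfa")
    graphs <- c(graphs, list(rdfa))
  }

  md <- extract_microdata(doc, base)
  if (n_triples(md) > 0) {
    syntaxes <- c(syntaxes, "microdata")
    graphs <- c(graphs, list(md))
  }

  graph <- normalize_schema_iris(do.call(graph_union, c(graphs, list(empty_graph()))))
  list(graph = graph, syntaxes_found = syntaxes)
}

parse_prefix_attr <- function(x) {
  if (is.na(x)) return(character())
  m <- str_match_all_pairs(x)
  m
}

str_match_all_pairs <- function(x) {
  toks <- str_split(str_trim(x), "\\s+")[[1]]
  out <- character()
  i <- 1L
  while (i < length(toks)) {
    pfx <- str_replace(toks[i], ":$", "")
    out[[pfx]] <- toks[i + 1L]
    i <- i + 2L
  }
  out
}

expand_rdfa_terms <- function(terms, vocab, prefixes) {
  toks <- str_split(str_trim(terms), "\\s+")[[1]]
  out <- vapply(toks, function(t) {
    m <- str_match(t, "^([A-Za-z][A-Za-z0-9._-]*):(.*)$")
    if (!is.na(m[2]) && m[2] %in% names(prefixes)) {
      return(paste0(prefixes[[m[2]]], m[3]))
    }
    if (is_absolute_iri(t)) return(t)
    if (!is.null(vocab) && !is.na(vocab)) return(paste0(vocab, t))
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  out[!is.na(out)]
}

# RDFa subset walker: vocab/prefix contexts, about, typeof, property with
# resource/href/src/content/text objects, and typeof+property chaining.
extract_rdfa <- function(doc, base) {
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$bnode <- blank_factory("r")
  emit <- function(s, p, o, kind, lang = NA_character_, dt = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <- list(
      subject = s, predicate = p, object = o,
      object_kind = kind, lang = lang, datatype = dt
    )
  }
  node_kind <- function(x) if (startsWith(x, "_:")) "blank" else "iri"

  walk_el <- function(el, subject, vocab, prefixes) {
    a <- function(name) xml2::xml_attr(el, name)
    if (!is.na(a("vocab"))) vocab <- a("vocab")
    px <- parse_prefix_attr(a("prefix"))
    if (length(px)) prefixes[names(px)] <- unname(px)

    about <- a("about")
    if (!is.na(about)) subject <- resolve_iri(about, base)
    res_attr <- a("resource") %|na|% a("href") %|na|% a("src")
    resource_obj <- if (!is.na(res_attr)) resolve_iri(res_attr, base) else NA_character_
    typeof <- a("typeof")
    property <- a("property")

    recurse_subject <- subject

    if (!is.na(typeof) && is.na(property)) {
      node <- if (!is.na(about)) subject else if (!is.na(resource_obj)) resource_obj else st$bnode()
      for (tp in expand_rdfa_terms(typeof, vocab, prefixes)) {
        emit(node, RDF_TYPE, tp, "iri")
      }
      recurse_subject <- node
    } else if (!is.na(property) && !is.na(typeof)) {
      node <- if (!is.na(about)) subject else if (!is.na(resource_obj)) resource_obj else st$bnode()
      for (p in expand_rdfa_terms(property, vocab, prefixes)) {
        emit(subject, p, node, node_kind(node))
      }
      for (tp in expand_rdfa_terms(typeof, vocab, prefixes)) {
        emit(node, RDF_TYPE, tp, "iri")
      }
      recurse_subject <- node
    } else if (!is.na(property)) {
      preds <- expand_rdfa_terms(property, vocab, prefixes)
      if (!is.na(resource_obj)) {
        for (p in preds) emit(subject, p, resource_obj, node_kind(resource_obj))
        recurse_subject <- resource_obj
      } else {
        content <- a("content")
        value <- if (!is.na(content)) content else str_trim(xml2::xml_text(el))
        dt_attr <- a("datatype")
        dt <- if (!is.na(dt_attr) && dt_attr != "") {
          expand_rdfa_terms(dt_attr, NULL, prefixes)[1]
        } else {
          NA_character_
        }
        lang <- a("lang") %|na|% a("xml:lang")
        for (p in preds) emit(subject, p, value, "literal", lang, dt)
        return(invisible(NULL)) # literal leaf: children are part of the value
      }
    } else if (!is.na(resource_obj)) {
      recurse_subject <- resource_obj
    }

    for (child in xml2::xml_children(el)) {
      walk_el(child, recurse_subject, vocab, prefixes)
    }
  }

  root <- xml2::xml_root(doc)
  base_subject <- if (!is.na(base)) strip_fragment(base) else st$bnode()
  walk_el(root, base_subject, NA_character_, fair_namespaces())
  if (length(st$rows) == 0) return(empty_graph())
  as_rdf_graph(bind_rows(lapply(st$rows, as_tibble)))
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

md_value <- function(el, base) {
  tag <- xml2::xml_name(el)
  a <- function(name) xml2::xml_attr(el, name)
  if (tag %in% c("a", "link", "area")) {
    return(list(resolve_iri(a("href"), base), "iri"))
  }
  if (tag %in% c("img", "audio", "video", "embed", "iframe", "source", "track")) {
    return(list(resolve_iri(a("src"), base), "iri"))
  }
  if (tag == "meta") return(list(a("content"), "literal"))
  if (tag == "time") {
    v <- a("datetime")
    return(list(if (is.na(v)) str_trim(xml2::xml_text(el)) else v, "literal"))
  }
  if (tag %in% c("data", "meter")) return(list(a("value"), "literal"))
  if (tag == "object") return(list(resolve_iri(a("data"), base), "iri"))
  list(str_trim(xml2::xml_text(el)), "literal")
}

# HTML microdata walker. itemref is not supported. Items without itemid
# become blank nodes, so tests against microdata assert triple counts and
# values, not node identity.
extract_microdata <- function(doc, base) {
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$bnode <- blank_factory("m")
  emit <- function(s, p, o, kind) {
    st$rows[[length(st$rows) + 1L]] <- list(
      subject = s, predicate = p, object = o,
      object_kind = kind, lang = NA_character_, datatype = NA_character_
    )
  }

  process_item <- function(el) {
    itemid <- xml2::xml_attr(el, "itemid")
    subj <- if (!is.na(itemid)) resolve_iri(itemid, base) else st$bnode()
    types <- xml2::xml_attr(el, "itemtype")
    vocab <- NA_character_
    if (!is.na(types)) {
      tps <- str_split(str_trim(types), "\\s+")[[1]]
      for (tp in tps) emit(subj, RDF_TYPE, tp, "iri")
      vocab <- iri_namespace(tps[1])
    }
    collect_props(el, subj, vocab)
    subj
  }

  collect_props <- function(el, subj, vocab) {
    for (child in xml2::xml_children(el)) {
      prop <- xml2::xml_attr(child, "itemprop")
      scoped <- !is.na(xml2::xml_attr(child, "itemscope"))
      if (!is.na(prop)) {
        nms <- str_split(str_trim(prop), "\\s+")[[1]]
        preds <- vapply(nms, function(nm) {
          if (is_absolute_iri(nm)) nm else if (!is.na(vocab)) paste0(vocab, nm) else NA_character_
        }, character(1), USE.NAMES = FALSE)
        if (scoped) {
          obj <- process_item(child)
          for (p in preds[!is.na(preds)]) {
            emit(subj, p, obj, if (startsWith(obj, "_:")) "blank" else "iri")
          }
          next
        }
        v <- md_value(child, base)
        for (p in preds[!is.na(preds)]) emit(subj, p, v[[1]], v[[2]])
        collect_props(child, subj, vocab)
      } else if (scoped) {
        process_item(child)
      } else {
        collect_props(child, subj, vocab)
      }
    }
  }

  tops <- xml2::xml_find_all(
    doc, "//*[@itemscope and not(@itemprop) and not(ancestor::*[@itemscope])]"
  )
  for (el in tops) process_item(el)
  if (length(st$rows) == 0) return(empty_graph())
  as_rdf_graph(bind_rows(lapply(st$rows, as_tibble)))
}
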