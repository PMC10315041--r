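# JSON-LD to triples. Covers the dialect used by schema.org-style embedded
# metadata: an inline @context (prefix map, term map with @id/@type, @vocab),
# a small set of well-known remote context URLs resolved from a built-in
# table (no network), @graph, @id, @type, nested node objects, arrays,
# @value/@language typed values. Full JSON-LD 1.1 expansion (reverse
# properties, @container maps, scoped contexts) is out of scope.

builtin_remote_contexts <- function() {
  list(
    "http://schema.org"   = list(vocab = "https://schema.org/"),
    "http://schema.org/"  = list(vocab = "https://schema.org/"),
    "https://schema.org"  = list(vocab = "https://schema.org/"),
    "https://schema.org/" = list(vocab = "https://schema.org/"),
    "https://schema.org/docs/jsonldcontext.json" = list(vocab = "https://schema.org/")
  )
}

new_jsonld_ctx <- function() {
  list(vocab = NULL, prefixes = character(), terms = list())
}

merge_jsonld_context <- function(ctx, spec) {
  if (is.null(spec)) return(ctx)
  if (is.character(spec) && length(spec) == 1) {
    known <- builtin_remote_contexts()[[spec]]
    if (!is.null(known)) {
      if (!is.null(known$vocab)) ctx$vocab <- known$vocab
    } else {
      warn(glue("Unknown remote JSON-LD context '{spec}'; terms may not expand"))
    }
    return(ctx)
  }
  if (is.list(spec) && is.null(names(spec))) {
    for (el in spec) ctx <- merge_jsonld_context(ctx, el)
    return(ctx)
  }
  for (key in names(spec)) {
    val <- spec[[key]]
    if (key == "@vocab") {
      ctx$vocab <- val
    } else if (key == "@base") {
      ctx$base <- val
    } else if (is.character(val) && length(val) == 1) {
      if (str_detect(val, "[/#:]$")) {
        ctx$prefixes[[key]] <- val
      } else {
        ctx$terms[[key]] <- list(id = val)
      }
    } else if (is.list(val) && !is.null(val[["@id"]])) {
      ctx$terms[[key]] <- list(id = val[["@id"]], type = val[["@type"]])
    }
  }
  ctx
}

jsonld_expand_key <- function(key, ctx) {
  if (startsWith(key, "@")) return(key)
  if (!is.null(ctx$terms[[key]])) key <- ctx$terms[[key]]$id
  m <- str_match(key, "^([A-Za-z][A-Za-z0-9._-]*):(.*)$")
  if (!is.na(m[2])) {
    if (m[2] %in% names(ctx$prefixes)) return(paste0(ctx$prefixes[[m[2]]], m[3]))
    if (is_absolute_iri(key)) return(key)
  }
  if (is_absolute_iri(key)) return(key)
  if (!is.null(ctx$vocab)) return(paste0(ctx$vocab, key))
  NA_character_
}

jsonld_term_type <- function(key, ctx) {
  t <- ctx$terms[[key]]$type
  if (is.null(t)) NA_character_ else t
}

#' Parse a JSON-LD document into triples
#'
#' @param x JSON-LD text (or an already-parsed list).
#' @param base Optional base IRI used to resolve relative `@id` references.
#' @param bnode_prefix Label prefix for generated blank nodes; callers
#'   extracting several annotation blocks use distinct prefixes so blank
#'   nodes from different blocks are never merged.
#' @return An `rdf_graph`.
#' @export
parse_jsonld <- function(x, base = NA_character_, bnode_prefix = "j") {
  doc <- if (is.character(x)) {
    jsonlite::fromJSON(paste(x, collapse = "\n"), simplifyVector = FALSE)
  } else {
    x
  }
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$bnode <- blank_factory(bnode_prefix)
  st$base <- base
  emit <- function(s, p, o, kind, lang = NA_character_, dt = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <- list(
      subject = s, predicate = p, object = as.character(o),
      object_kind = kind, lang = lang, datatype = dt
    )
  }

  node_id <- function(obj, ctx) {
    id <- obj[["@id"]]
    if (is.null(id)) return(st$bnode())
    id <- as.character(id)
    resolved <- resolve_iri(id, ctx$base %||% st$base)
    resolved
  }

  xsd <- function(local) paste0(fair_namespaces()[["xsd"]], local)

  value_literal <- function(v) {
    if (is.logical(v)) {
      list(tolower(as.character(v)), xsd("boolean"))
    } else if (is.numeric(v)) {
      if (v == trunc(v) && !grepl("[.eE]", format(v, scientific = FALSE))) {
        list(format(v, scientific = FALSE), xsd("integer"))
      } else {
        list(format(v, scientific = FALSE), xsd("double"))
      }
    } else {
      list(as.character(v), NA_character_)
    }
  }

  process_node <- function(obj, ctx) {
    local_ctx <- merge_jsonld_context(ctx, obj[["@context"]])
    if (!is.null(obj[["@graph"]]) && is.null(obj[["@id"]])) {
      for (n in obj[["@graph"]]) process_node(n, local_ctx)
      return(st$bnode())
    }
    subj <- node_id(obj, local_ctx)
    types <- obj[["@type"]]
    if (!is.null(types)) {
      for (tp in unlist(types)) {
        iri <- jsonld_expand_key(tp, local_ctx)
        if (!is.na(iri)) emit(subj, RDF_TYPE, iri, "iri")
      }
    }
    handle_value <- function(subj, pred, v, key, ctx) {
      if (is.list(v) && is.null(names(v))) {
        for (el in v) handle_value(subj, pred, el, key, ctx)
      } else if (is.list(v)) {
        if (!is.null(v[["@value"]])) {
          lit <- value_literal(v[["@value"]])
          dt <- v[["@type"]]
          dt <- if (is.null(dt)) lit[[2]] else jsonld_expand_key(dt, ctx)
          lang <- v[["@language"]] %||% NA_character_
          emit(subj, pred, lit[[1]], "literal", lang, dt %||% NA_character_)
        } else if (!is.null(v[["@id"]]) &&
                     length(setdiff(names(v), c("@id", "@context"))) == 0) {
          emit(subj, pred, node_id(v, ctx), "iri")
        } else {
          child <- process_node(v, ctx)
          kind <- if (startsWith(child, "_:")) "blank" else "iri"
          emit(subj, pred, child, kind)
        }
      } else if (identical(jsonld_term_type(key, ctx), "@id") && is.character(v)) {
        emit(subj, pred, resolve_iri(v, ctx$base %||% st$base), "iri")
      } else {
        lit <- value_literal(v)
        emit(subj, pred, lit[[1]], "literal", NA_character_, lit[[2]])
      }
    }
    for (key in setdiff(names(obj), c("@context", "@id", "@type", "@graph"))) {
      pred <- jsonld_expand_key(key, local_ctx)
      if (is.na(pred)) next
      handle_value(subj, pred, obj[[key]], key, local_ctx)
    }
    subj
  }

  roots <- if (is.list(doc) && is.null(names(doc))) doc else list(doc)
  ctx0 <- new_jsonld_ctx()
  for (r in roots) {
    if (is.list(r)) process_node(r, ctx0)
  }
  if (length(st$rows) == 0) return(empty_graph())
  as_rdf_graph(bind_rows(lapply(st$rows, as_tibble)))
}
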