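# Community metadata profiles and SHACL shape generation. A profile lists
# the properties a typed entity should carry, by marginality: minimum
# properties become SHACL property shapes with Violation severity,
# recommended properties become Warning-severity shapes; optional
# properties are parsed but generate no constraint. All generated
# constraints are presence checks (sh:minCount 1) instantiated from one
# shape template.

#' Create a community profile specification
#'
#' @param name Profile name.
#' @param source_url Absolute URL identifying the profile (matched against
#'   `dct:conformsTo` declarations).
#' @param target_class IRI of the class the profile targets.
#' @param minimum_properties,recommended_properties Disjoint character
#'   vectors of property IRIs.
#' @param optional_properties Parsed for completeness; generates no
#'   constraint.
#' @return A `profile_spec` object.
#' @export
profile_spec <- function(name, source_url, target_class,
                         minimum_properties = character(),
                         recommended_properties = character(),
                         optional_properties = character()) {
  target_class <- expand_curie(target_class)
  minimum_properties <- expand_curie(minimum_properties)
  recommended_properties <- expand_curie(recommended_properties)
  if (!is_absolute_iri(target_class)) {
    abort(glue("target_class must be an absolute IRI, got '{target_class}'"),
      class = "faircheckr_contract_error"
    )
  }
  overlap <- intersect(minimum_properties, recommended_properties)
  if (length(overlap)) {
    abort(glue("minimum and recommended property sets overlap: {overlap[1]}"),
      class = "faircheckr_contract_error"
    )
  }
  structure(
    list(
      name = name, source_url = source_url, target_class = target_class,
      minimum_properties = minimum_properties,
      recommended_properties = recommended_properties,
      optional_properties = expand_curie(optional_properties)
    ),
    class = "profile_spec"
  )
}

#' @export
print.profile_spec <- function(x, ...) {
  cat("<profile_spec>", x$name, "\n")
  cat("  target:", compact_iri(x$target_class), "\n")
  cat("  minimum:", length(x$minimum_properties),
      "| recommended:", length(x$recommended_properties), "\n")
  invisible(x)
}

profile_key <- function(doc, local) {
  # tolerate namespaced keys ("bioschemas:targetClass") in profile documents
  hits <- names(doc)[sub("^.*[:#/]", "", names(doc)) == local]
  if (length(hits)) doc[[hits[1]]] else NULL
}

#' Parse a machine-readable profile specification (JSON-LD dialect)
#'
#' Reads profile documents in the JSON-LD dialect used by the
#' specification files shipped with this package (see
#' `inst/extdata/profiles/`): a target class plus a property list with
#' per-property marginality labels (`Minimum`, `Recommended`, `Optional`,
#' case-insensitive).
#'
#' @param x Document text, file path, or parsed list.
#' @return A [profile_spec()].
#' @export
parse_profile <- function(x) {
  doc <- if (is.list(x)) {
    x
  } else if (length(x) == 1 && file.exists(x)) {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(paste(x, collapse = "\n"), simplifyVector = FALSE)
  }
  as_iri <- function(v) {
    if (is.list(v)) v <- v[["@id"]]
    expand_curie(as.character(v))
  }
  target <- profile_key(doc, "targetClass")
  if (is.null(target)) {
    abort("profile document declares no target class",
      class = "faircheckr_parse_error"
    )
  }
  name <- profile_key(doc, "name") %||% sub("^.*/profiles/([^/]+).*$", "\\1",
    doc[["@id"]] %||% "profile"
  )
  props <- profile_key(doc, "properties") %||% list()
  buckets <- list(minimum = character(), recommended = character(), optional = character())
  for (p in props) {
    iri <- as_iri(profile_key(p, "property") %||% p[["@id"]])
    marg_raw <- as.character(profile_key(p, "marginality") %||% "")
    marg <- tolower(marg_raw)
    if (!marg %in% names(buckets)) {
      abort(glue("unknown marginality label '{marg_raw}' for property {iri}"),
        class = "faircheckr_parse_error"
      )
    }
    buckets[[marg]] <- c(buckets[[marg]], iri)
  }
  profile_spec(
    name = as.character(name),
    source_url = as.character(doc[["@id"]] %||% NA_character_),
    target_class = as_iri(target),
    minimum_properties = buckets$minimum,
    recommended_properties = buckets$recommended,
    optional_properties = buckets$optional
  )
}

#' Profiles shipped with the package
#'
#' Frozen fixture copies of two community profiles (a Gene profile and a
#' ComputationalTool profile); their `source_url` records the upstream
#' profile URL for provenance. Refreshing from a live specification
#' repository is deliberately not automatic.
#'
#' @return A list of [profile_spec()]s.
#' @export
default_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "faircheckr")
  map(list.files(dir, pattern = "\\.jsonld$", full.names = TRUE), parse_profile)
}

SH <- function(local) paste0(fair_namespaces()[["sh"]], local)

#' Generate the SHACL shape graph for a profile
#'
#' Instantiates the single shape template: one node shape targeting the
#' profile's class; per minimum property a Violation-severity property
#' shape, per recommended property a Warning-severity shape, each with a
#' `sh:minCount 1` presence constraint. Property order is sorted so a
#' fixed profile always yields an identical shape graph.
#'
#' @param profile A [profile_spec()].
#' @return An [rdf_graph()] holding the shapes.
#' @export
generate_shape <- function(profile) {
  shape <- paste0("urn:faircheckr:shape:", gsub("[^A-Za-z0-9._-]", "-", profile$name))
  xsd_int <- paste0(fair_namespaces()[["xsd"]], "integer")
  rows <- list(
    list(shape, RDF_TYPE, SH("NodeShape"), "iri", NA, NA),
    list(shape, SH("targetClass"), profile$target_class, "iri", NA, NA)
  )
  add_prop <- function(prop, severity, phrase, label) {
    b <- paste0("_:", label)
    rows[[length(rows) + 1L]] <<- list(shape, SH("property"), b, "blank", NA, NA)
    rows[[length(rows) + 1L]] <<- list(b, SH("path"), prop, "iri", NA, NA)
    rows[[length(rows) + 1L]] <<- list(b, SH("minCount"), "1", "literal", NA, xsd_int)
    rows[[length(rows) + 1L]] <<- list(b, SH("severity"), SH(severity), "iri", NA, NA)
    rows[[length(rows) + 1L]] <<- list(
      b, SH("message"),
      glue("Property {compact_iri(prop)} {phrase} provided."), "literal", NA, NA
    )
  }
  mins <- sort(profile$minimum_properties)
  recs <- sort(profile$recommended_properties)
  for (i in seq_along(mins)) add_prop(mins[i], "Violation", "must be", paste0("min", i))
  for (i in seq_along(recs)) add_prop(recs[i], "Warning", "should be", paste0("rec", i))
  g <- bind_rows(lapply(rows, function(r) {
    tibble(
      subject = r[[1]], predicate = r[[2]], object = as.character(r[[3]]),
      object_kind = r[[4]], lang = NA_character_,
      datatype = if (is.na(r[[6]])) NA_character_ else r[[6]]
    )
  }))
  as_rdf_graph(g)
}

#' Select the applicable profile for an entity
#'
#' Follows the provider's own `dct:conformsTo` declaration when it names a
#' known profile; otherwise matches the entity's `rdf:type` against
#' profile target classes. Ties are broken by the larger count of
#' already-present minimum properties, then by profile name.
#'
#' @param entity_graph The entity's [rdf_graph()].
#' @param entity The focus entity IRI (or blank node label).
#' @param available List of [profile_spec()]s.
#' @return A [profile_spec()] or `NULL` when no profile applies.
#' @export
select_profile <- function(entity_graph, entity, available = default_profiles()) {
  g <- entity_graph
  conforms <- g$object[g$subject == entity &
    g$predicate == expand_curie("dct:conformsTo")]
  if (length(conforms)) {
    for (p in available) {
      if (!is.na(p$source_url) && p$source_url %in% conforms) return(p)
    }
  }
  types <- g$object[g$subject == entity & g$predicate == RDF_TYPE &
    g$object_kind == "iri"]
  cands <- keep(available, function(p) p$target_class %in% types)
  if (length(cands) == 0) return(NULL)
  if (length(cands) == 1) return(cands[[1]])
  present <- vapply(cands, function(p) {
    sum(p$minimum_properties %in% g$predicate[g$subject == entity])
  }, numeric(1))
  nms <- vapply(cands, function(p) p$name, character(1))
  cands[[order(-present, nms)[1]]]
}

parse_shape_graph <- function(shape) {
  node_shapes <- shape$subject[shape$predicate == RDF_TYPE &
    shape$object == SH("NodeShape")]
  map(unique(node_shapes), function(ns) {
    target <- shape$object[shape$subject == ns & shape$predicate == SH("targetClass")]
    pshapes <- shape$object[shape$subject == ns & shape$predicate == SH("property")]
    props <- map_dfr(pshapes, function(b) {
      val <- function(p) {
        v <- shape$object[shape$subject == b & shape$predicate == SH(p)]
        if (length(v)) v[1] else NA_character_
      }
      mc <- val("minCount")
      tibble(
        path = val("path"),
        min_count = if (is.na(mc)) 1L else as.integer(mc),
        severity = val("severity"),
        message = val("message")
      )
    })
    list(shape_iri = ns, target_class = target, properties = props)
  })
}

#' Validate a graph against a generated SHACL shape
#'
#' Focus nodes are the entities typed with the shape's target class (or
#' the explicit `focus`). A minimum property with zero occurrences on a
#' focus node yields a Violation result; a recommended property likewise
#' yields a Warning. The report is deterministic.
#'
#' @param graph The data [rdf_graph()].
#' @param shape A shape graph from [generate_shape()] (or compatible).
#' @param focus Optional explicit focus node(s).
#' @return A `shape_report` tibble with columns `focus`, `property`,
#'   `severity`, `message`, and attributes `conforms`, `n_violations`,
#'   `n_warnings`, `n_focus`.
#' @export
validate_shape <- function(graph, shape, focus = NULL) {
  shapes <- parse_shape_graph(shape)
  if (length(shapes) == 0) {
    abort("malformed shape graph: no sh:NodeShape found",
      class = "faircheckr_validation_error"
    )
  }
  rows <- list()
  n_focus <- 0L
  for (s in shapes) {
    focus_nodes <- if (!is.null(focus)) {
      focus
    } else {
      sort(unique(graph$subject[graph$predicate == RDF_TYPE &
        graph$object %in% s$target_class]))
    }
    n_focus <- n_focus + length(focus_nodes)
    if (nrow(s$properties) == 0) next
    for (fn in focus_nodes) {
      present <- graph$predicate[graph$subject == fn]
      for (i in seq_len(nrow(s$properties))) {
        p <- s$properties[i, ]
        if (sum(present == p$path) < p$min_count) {
          rows[[length(rows) + 1L]] <- tibble(
            focus = fn, property = p$path,
            severity = sub(".*#", "", p$severity),
            message = glue("{fn}: {p$message}")
          )
        }
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(focus = character(), property = character(),
           severity = character(), message = character())
  }
  out <- arrange(out, .data$focus, .data$severity, .data$property)
  attr(out, "conforms") <- !any(out$severity == "Violation")
  attr(out, "n_violations") <- sum(out$severity == "Violation")
  attr(out, "n_warnings") <- sum(out$severity == "Warning")
  attr(out, "n_focus") <- n_focus
  class(out) <- c("shape_report", class(tibble()))
  out
}

#' @export
print.shape_report <- function(x, ...) {
  cat(
    "# Shape report:", attr(x, "n_violations"), "violation(s),",
    attr(x, "n_warnings"), "warning(s);",
    if (attr(x, "conforms")) "conformant\n" else "NOT conformant\n"
  )
  NextMethod()
}

#' Turn a shape report into human-readable messages
#'
#' Violations (missing minimum properties) are phrased as requirements
#' ("must be"); warnings (missing recommended properties) as improvements
#' ("should be"). Each message names the entity and the missing property
#' in prefixed form.
#'
#' @param report A `shape_report` from [validate_shape()].
#' @return Character vector of messages (empty for a clean report).
#' @export
humanize <- function(report) {
  if (nrow(report) == 0) return(character())
  vapply(seq_len(nrow(report)), function(i) {
    phrase <- if (report$severity[i] == "Violation") "must be" else "should be"
    glue("{report$focus[i]}: property {compact_iri(report$property[i])} {phrase} provided.")
  }, character(1))
}

#' Write generated shapes to Turtle files
#'
#' @param profiles List of [profile_spec()]s.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
emit_shapes <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(profiles, function(p) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "-", p$name), "-shape.ttl"))
    write_turtle(generate_shape(p), path)
    path
  }, character(1))
  invisible(paths)
}
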