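# Reporting: per-resource reports with recommendations, batch aggregation
# into metric-combination counts (UpSet-style exact partitions) and
# profile-completeness statistics, and JSON/CSV/markdown export.

#' Metric pass/fail matrix from a set of evaluations
#'
#' @param results A list of `fair_result` tibbles (from [evaluate_all()]),
#'   optionally named by resource key.
#' @return A tibble with a `resource` column and one logical column per
#'   metric, in canonical metric order.
#' @export
metric_matrix <- function(results) {
  if (length(results) == 0) {
    cols <- c(list(resource = character()),
              setNames(rep(list(logical()), length(METRIC_IDS)), METRIC_IDS))
    return(as_tibble(cols))
  }
  nms <- names(results) %||% as.character(seq_along(results))
  if (is.null(names(results))) {
    nms <- map_chr(results, function(r) attr(r, "subject_url") %||% NA_character_)
    if (anyNA(nms)) nms <- as.character(seq_along(results))
  }
  rows <- map2(results, nms, function(r, nm) {
    v <- setNames(as.list(r$status == "pass"), r$metric_id)
    as_tibble(c(list(resource = nm), v))
  })
  bind_rows(rows)
}

#' Count resources per identical metric pass/fail combination
#'
#' The exact partition of resources by metric vector (the input to an
#' UpSet plot): each combination is the set of passed metrics, and the
#' counts sum to the number of resources.
#'
#' @param vectors A metric matrix (see [metric_matrix()]) or a list of
#'   equally-long named logical vectors.
#' @return A tibble with columns `combination` (passed metric ids joined
#'   by `+`, `"(none)"` when empty) and `n`, sorted by decreasing count.
#' @export
summarize_combinations <- function(vectors) {
  if (is.data.frame(vectors)) {
    mat <- vectors[, setdiff(names(vectors), "resource"), drop = FALSE]
  } else {
    lens <- lengths(vectors)
    if (length(unique(lens)) > 1) {
      abort("ragged metric vectors: all vectors must have the same length/order",
        class = "faircheckr_contract_error"
      )
    }
    if (length(vectors) == 0) {
      return(tibble(combination = character(), n = integer()))
    }
    mat <- as_tibble(do.call(rbind, lapply(vectors, as.logical)), .name_repair = "minimal")
    names(mat) <- names(vectors[[1]]) %||% paste0("m", seq_len(ncol(mat)))
  }
  if (nrow(mat) == 0) return(tibble(combination = character(), n = integer()))
  keys <- apply(mat, 1, function(row) {
    ids <- names(mat)[as.logical(row)]
    if (length(ids) == 0) "(none)" else paste(ids, collapse = "+")
  })
  out <- count(tibble(combination = keys), .data$combination, name = "n")
  arrange(out, desc(.data$n), .data$combination)
}

#' Recommended-property completeness of a validated entity
#'
#' The fraction of the profile's recommended properties present:
#' `(|recommended| - warnings) / |recommended|`. Profiles without
#' recommended properties score 1 with the `no_recommended` attribute set.
#'
#' @param report A `shape_report` produced against `profile`.
#' @param profile The [profile_spec()] validated against.
#' @return A fraction in `[0, 1]` (attribute `no_recommended` flags the
#'   degenerate case).
#' @export
completeness <- function(report, profile) {
  r <- length(profile$recommended_properties)
  if (r == 0) {
    return(structure(1, no_recommended = TRUE))
  }
  w <- attr(report, "n_warnings") %||% sum(report$severity == "Warning")
  structure((r - w) / r, no_recommended = FALSE)
}

fair_cookbook <- function(recipe) {
  paste0("fair-cookbook-recipe-", recipe)
}

#' Recommendation text for a metric outcome
#'
#' Failing metrics yield actionable guidance (with training-resource link
#' identifiers, e.g. FAIR Cookbook recipes); passing metrics yield an
#' empty recommendation.
#'
#' @param metric_id A canonical metric id.
#' @param status `"pass"`, `"fail"` or `"error"`.
#' @return A list with elements `text` and `links` (character vectors).
#' @export
recommendation_for <- function(metric_id, status) {
  if (!metric_id %in% METRIC_IDS) {
    abort(glue("Unknown metric id '{metric_id}'"), class = "faircheckr_contract_error")
  }
  if (status == "pass") return(list(text = "", links = character()))
  rec <- switch(metric_id,
    "F1A" = list(
      text = "Identify the resource with a globally unique, syntactically valid absolute URL.",
      links = character()
    ),
    "F1B" = list(
      text = paste(
        "Assign a persistent identifier (e.g. a DOI or an Identifiers.org-registered",
        "scheme) or expose one through an identifier property; see the FAIR Cookbook",
        "recipe on unique and persistent identifiers."
      ),
      links = fair_cookbook(1)
    ),
    "F2A" = list(
      text = paste(
        "Embed structured metadata in the page, e.g. a JSON-LD script block with",
        "Schema.org markup; the FAIR Cookbook recipe on Search Engine Optimisation",
        "shows worked examples."
      ),
      links = fair_cookbook(8)
    ),
    "F2B" = list(
      text = paste(
        "Describe the resource with terms from shared, registered vocabularies",
        "(Schema.org, Dublin Core, domain ontologies); the FAIR Cookbook",
        "introductions to terminologies and ontology selection can guide the choice."
      ),
      links = fair_cookbook(c(3, 4))
    ),
    "A1.1" = list(
      text = "Serve the resource over an open, standardised protocol (http/https/ftp) at a resolvable URL.",
      links = character()
    ),
    "A1.2" = list(
      text = "Add machine-readable access information, e.g. dct:accessRights, odrl:hasPolicy or a download/endpoint URL (dcat:accessURL, schema:downloadUrl).",
      links = character()
    ),
    "I1" = list(
      text = "Expose metadata in a formal knowledge-representation language: RDF embedded as JSON-LD, RDFa or microdata, or a native RDF serialization.",
      links = fair_cookbook(8)
    ),
    "I2" = list(
      text = paste(
        "Use vocabularies registered in community registries for every namespace in",
        "your metadata; the FAIR Cookbook terminology recipes help select FAIR",
        "vocabularies."
      ),
      links = fair_cookbook(c(3, 4))
    ),
    "I3" = list(
      text = "Link to related resources with qualified references: IRIs pointing at external entities (citations, derived-from links, related datasets).",
      links = character()
    ),
    "R1.1" = list(
      text = paste(
        "Declare a machine-readable license with one of the following properties:",
        "schema:license, dct:license, doap:license, dbpedia-owl:license or cc:license."
      ),
      links = character()
    ),
    "R1.2" = list(
      text = "Attach provenance metadata: authorship and versioning via prov:*, pav:* or dct:creator/contributor/publisher, schema:author and related properties.",
      links = character()
    ),
    "R1.3" = list(
      text = "Annotate with community-standard domain vocabularies (e.g. the EDAM ontology for bioinformatics resources) or conform to a community metadata profile.",
      links = character()
    )
  )
  rec
}

#' Assemble a batch summary from per-resource evaluations
#'
#' @param results Named list of `fair_result` tibbles (names = resource keys).
#' @param completeness_by_resource Optional tibble with columns `resource`
#'   and `completeness` (profile-completeness fractions).
#' @return A `fair_batch_summary`: resource/metric matrix, combination
#'   counts, completeness statistics.
#' @export
batch_summary <- function(results, completeness_by_resource = NULL) {
  mat <- metric_matrix(results)
  combos <- summarize_combinations(mat)
  mean_c <- if (!is.null(completeness_by_resource) && nrow(completeness_by_resource)) {
    mean(completeness_by_resource$completeness)
  } else {
    NA_real_
  }
  structure(
    list(
      n_resources = nrow(mat),
      n_evaluations = nrow(mat) * (ncol(mat) - 1L),
      matrix = mat,
      combination_counts = combos,
      completeness = completeness_by_resource,
      mean_completeness = mean_c
    ),
    class = "fair_batch_summary"
  )
}

#' @export
print.fair_batch_summary <- function(x, ...) {
  cat("# FAIR batch summary:", x$n_resources, "resource(s),",
      x$n_evaluations, "metric evaluations\n")
  cat("# distinct metric combinations:", nrow(x$combination_counts), "\n")
  if (!is.na(x$mean_completeness)) {
    cat("# mean profile completeness:", sprintf("%.1f%%", 100 * x$mean_completeness), "\n")
  }
  invisible(x)
}

#' UpSet-ready membership matrix
#'
#' @param summary A `fair_batch_summary`.
#' @return A tibble: one row per resource, one 0/1 column per metric.
#' @export
membership_matrix <- function(summary) {
  mat <- summary$matrix
  mutate(mat, across(-"resource", as.integer))
}

# ---- export ----------------------------------------------------------------

result_rows <- function(x) {
  tibble(
    resource = attr(x, "subject_url") %||% NA_character_,
    metric_id = x$metric_id,
    status = x$status,
    n_evidence = x$n_evidence,
    recommendation = x$recommendation
  )
}

#' Serialize a report or batch summary
#'
#' @param x A `fair_result` or `fair_batch_summary`.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @param path Optional output file.
#' @return The serialized document as a string (invisibly when written to
#'   `path`).
#' @export
export_report <- function(x, format = c("json", "csv", "markdown"), path = NULL) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(glue("unknown export format '{format[1]}'"), class = "faircheckr_contract_error")
  })
  txt <- if (inherits(x, "fair_result")) {
    export_result(x, format)
  } else if (inherits(x, "fair_batch_summary")) {
    export_batch(x, format)
  } else {
    abort("export_report expects a fair_result or fair_batch_summary",
      class = "faircheckr_contract_error"
    )
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

csv_text <- function(df) {
  paste0(readr::format_csv(df, eol = "\n"))
}

export_result <- function(x, format) {
  rows <- result_rows(x)
  switch(format,
    json = jsonlite::toJSON(
      list(
        resource = attr(x, "subject_url"),
        n_pass = sum(x$status == "pass"),
        metrics = rows[, c("metric_id", "status", "n_evidence", "recommendation")]
      ),
      auto_unbox = TRUE, pretty = TRUE
    ),
    csv = csv_text(rows),
    markdown = paste0(
      "# FAIR assessment: ", attr(x, "subject_url"), "\n\n",
      sum(x$status == "pass"), " of ", nrow(x), " metrics passed\n\n",
      "| metric | status | evidence | recommendation |\n",
      "|---|---|---|---|\n",
      paste(sprintf(
        "| %s | %s | %d | %s |",
        rows$metric_id, rows$status, rows$n_evidence, rows$recommendation
      ), collapse = "\n"),
      "\n"
    )
  )
}

export_batch <- function(x, format) {
  switch(format,
    json = jsonlite::toJSON(
      list(
        n_resources = x$n_resources,
        n_evaluations = x$n_evaluations,
        mean_completeness = x$mean_completeness,
        combination_counts = x$combination_counts,
        matrix = membership_matrix(x)
      ),
      auto_unbox = TRUE, pretty = TRUE, na = "null"
    ),
    csv = {
      long <- tidyr::pivot_longer(x$matrix, -"resource",
        names_to = "metric_id", values_to = "pass"
      )
      csv_text(long)
    },
    markdown = paste0(
      "# FAIR batch summary\n\n",
      x$n_resources, " resources, ", x$n_evaluations, " evaluations\n\n",
      "| combination | n |\n|---|---|\n",
      paste(sprintf("| %s | %d |", x$combination_counts$combination,
                    x$combination_counts$n), collapse = "\n"),
      "\n"
    )
  )
}

# ---- tidiers and plots -----------------------------------------------------

#' @exportS3Method generics::tidy
tidy.fair_result <- function(x, ...) {
  tibble(
    metric_id = x$metric_id, status = x$status, priority = x$priority,
    test_kind = x$test_kind, n_evidence = x$n_evidence,
    recommendation = x$recommendation
  )
}

#' @exportS3Method generics::glance
glance.fair_result <- function(x, ...) {
  tibble(
    resource = attr(x, "subject_url") %||% NA_character_,
    n_metrics = nrow(x),
    n_pass = sum(x$status == "pass"),
    n_fail = sum(x$status == "fail"),
    n_error = sum(x$status == "error")
  )
}

#' @exportS3Method generics::tidy
tidy.fair_batch_summary <- function(x, ...) {
  tidyr::pivot_longer(x$matrix, -"resource",
    names_to = "metric_id", values_to = "pass"
  )
}

#' @exportS3Method generics::glance
glance.fair_batch_summary <- function(x, ...) {
  tibble(
    n_resources = x$n_resources,
    n_evaluations = x$n_evaluations,
    n_combinations = nrow(x$combination_counts),
    mean_completeness = x$mean_completeness
  )
}

#' @exportS3Method generics::tidy
tidy.shape_report <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.shape_report <- function(x, ...) {
  tibble(
    conforms = attr(x, "conforms"),
    n_violations = attr(x, "n_violations"),
    n_warnings = attr(x, "n_warnings"),
    n_focus = attr(x, "n_focus")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.fair_result <- function(object, ...) {
  df <- tidy(object)
  df$metric_id <- factor(df$metric_id, levels = rev(METRIC_IDS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$metric_id,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(pass = "#2b8cbe", fail = "grey70",
                                          error = "#d7301f")) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "FAIR metric assessment",
      subtitle = attr(object, "subject_url")
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fair_batch_summary <- function(object, ...) {
  df <- object$combination_counts
  df$combination <- factor(df$combination, levels = rev(df$combination))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$combination)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(
      x = "resources", y = "validated metric combination",
      title = "Metric combinations across the batch"
    ) +
    ggplot2::theme_minimal()
}
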