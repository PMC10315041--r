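# Shared test helpers: independent oracles and small constructors.

# linear-scan existential oracle for property-presence semantics,
# independent of the generated-query route
oracle_any_property <- function(graph, props) {
  if (nrow(graph) == 0) return(FALSE)
  hit <- FALSE
  for (i in seq_len(nrow(graph))) {
    if (graph$predicate[i] %in% props) hit <- TRUE
  }
  hit
}

# brute-force reachability oracle for dump partitioning: triples whose
# subject is reachable from `root` in at most `depth` object-following hops
oracle_reachable_triples <- function(graph, root, depth = 3, stop_at = character()) {
  nodes <- root
  keep <- rep(FALSE, nrow(graph))
  for (d in seq_len(depth)) {
    hit <- graph$subject %in% nodes
    keep <- keep | hit
    nxt <- unique(graph$object[hit & graph$object_kind %in% c("iri", "blank")])
    nodes <- setdiff(nxt, c(nodes, stop_at))
    if (length(nodes) == 0) break
  }
  graph[keep, ]
}

graphs_equal <- function(a, b) {
  a <- as.data.frame(faircheckr:::sort_graph(a))
  b <- as.data.frame(faircheckr:::sort_graph(b))
  isTRUE(all.equal(a, b, check.attributes = FALSE))
}

tool_profile <- function() {
  purrr::detect(default_profiles(), function(p) p$name == "ComputationalTool")
}

gene_profile <- function() {
  purrr::detect(default_profiles(), function(p) p$name == "Gene")
}

# resource assembled as if harvested from a 200-OK page
page_resource <- function(html, url = "https://tools.example.org/phyml",
                          status = 200L) {
  ex <- extract_embedded(html, url)
  make_resource(url, ex$graph,
    http_status = status,
    syntaxes_found = ex$syntaxes_found
  )
}

# a conformant entity graph for a profile: every minimum and recommended
# property once, plus the type triple
conformant_entity <- function(profile, subject = "https://entities.example.org/e1") {
  props <- c(profile$minimum_properties, profile$recommended_properties)
  as_rdf_graph(tibble::tibble(
    subject = subject,
    predicate = c(faircheckr:::RDF_TYPE, props),
    object = c(profile$target_class, paste0("v", seq_along(props))),
    object_kind = c("iri", rep("literal", length(props))),
    lang = NA_character_, datatype = NA_character_
  ))
}

all_pass_vector <- function() {
  setNames(rep(TRUE, 12), faircheckr:::METRIC_IDS)
}

vec_with <- function(...) {
  v <- all_pass_vector()
  drop <- c(...)
  v[drop] <- FALSE
  v
}
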