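test_that("the Gene profile document parses into the expected buckets", {
  gene <- gene_profile()
  expect_true(all(c("https://schema.org/identifier", "https://schema.org/name")
  %in% gene$minimum_properties))
  expect_true(all(c("https://schema.org/description", "https://schema.org/url")
  %in% gene$recommended_properties))
  expect_equal(gene$target_class, "https://schema.org/Gene")
})

test_that("profile parsing validates target class and marginality labels", {
  doc_no_target <- '{"@id": "https://p.org/x", "name": "X",
    "properties": [{"property": "https://schema.org/name", "marginality": "Minimum"}]}'
  expect_error(parse_profile(doc_no_target), class = "faircheckr_parse_error")

  doc_bad_marg <- '{"@id": "https://p.org/x", "name": "X",
    "targetClass": "https://schema.org/Thing",
    "properties": [{"property": "https://schema.org/name", "marginality": "Sometimes"}]}'
  expect_error(parse_profile(doc_bad_marg), "Sometimes")

  doc_no_rec <- '{"@id": "https://p.org/x", "name": "X",
    "targetClass": "https://schema.org/Thing",
    "properties": [{"property": "https://schema.org/name", "marginality": "Minimum"}]}'
  p <- parse_profile(doc_no_rec)
  expect_length(p$recommended_properties, 0)
})

test_that("generated profile documents round-trip through the parser", {
  doc <- make_profile_document(
    "GeneLike", "schema:Gene",
    min_props = c("schema:identifier", "schema:name"),
    rec_props = c("schema:description", "schema:url")
  )
  p <- parse_profile(doc)
  expect_equal(p$name, "GeneLike")
  expect_equal(p$minimum_properties, c(
    "https://schema.org/identifier", "https://schema.org/name"
  ))
  expect_equal(p$recommended_properties, c(
    "https://schema.org/description", "https://schema.org/url"
  ))
  expect_error(
    make_profile_document("X", "schema:Gene",
      min_props = "schema:name", rec_props = "schema:name"
    ),
    class = "faircheckr_contract_error"
  )
})

test_that("shape counts equal the profile's marginality bucket sizes", {
  sev <- function(shape, s) sum(shape$predicate == faircheckr:::SH("severity") &
    shape$object == faircheckr:::SH(s))
  p <- profile_spec("T", "https://p.org/T", "schema:Thing",
    minimum_properties = c("schema:a", "schema:b"),
    recommended_properties = c("schema:c", "schema:d", "schema:e")
  )
  sh <- generate_shape(p)
  expect_equal(sev(sh, "Violation"), 2)
  expect_equal(sev(sh, "Warning"), 3)

  none_rec <- profile_spec("U", "https://p.org/U", "schema:Thing",
    minimum_properties = "schema:a"
  )
  expect_equal(sev(generate_shape(none_rec), "Warning"), 0)

  gene_shape <- generate_shape(gene_profile())
  viol_paths <- gene_shape$object[gene_shape$predicate == faircheckr:::SH("path")]
  expect_true(all(c("https://schema.org/identifier", "https://schema.org/name")
  %in% viol_paths))
})

test_that("shape emission to Turtle is stable for a fixed profile", {
  d <- withr::local_tempdir()
  p1 <- emit_shapes(list(gene_profile()), file.path(d, "a"))
  p2 <- emit_shapes(list(gene_profile()), file.path(d, "b"))
  expect_identical(readLines(p1), readLines(p2))
  reread <- read_rdf(p1, "turtle")
  expect_true(graphs_equal(reread, generate_shape(gene_profile())))
})

test_that("profile selection honors conformsTo, then type, then ties", {
  profs <- default_profiles()
  gene_url <- gene_profile()$source_url
  declared <- graph_union(
    rdf_graph("https://e.org/x", "dct:conformsTo", gene_url),
    rdf_graph("https://e.org/x", "rdf:type", "schema:SoftwareApplication")
  )
  expect_equal(select_profile(declared, "https://e.org/x", profs)$name, "Gene")

  typed <- rdf_graph("https://e.org/x", "rdf:type", "schema:SoftwareApplication")
  expect_equal(select_profile(typed, "https://e.org/x", profs)$name, "ComputationalTool")

  unmatched <- rdf_graph("https://e.org/x", "rdf:type", "schema:Event")
  expect_null(select_profile(unmatched, "https://e.org/x", profs))

  # tie on type: broken by present minimum properties, then name
  p1 <- profile_spec("Alpha", "https://p.org/a", "schema:Thing",
    minimum_properties = c("schema:name", "schema:url")
  )
  p2 <- profile_spec("Beta", "https://p.org/b", "schema:Thing",
    minimum_properties = c("schema:identifier", "schema:version")
  )
  g <- graph_union(
    rdf_graph("https://e.org/x", "rdf:type", "schema:Thing"),
    rdf_graph("https://e.org/x", "schema:identifier", "i"),
    rdf_graph("https://e.org/x", "schema:version", "1")
  )
  expect_equal(select_profile(g, "https://e.org/x", list(p1, p2))$name, "Beta")
  bare <- rdf_graph("https://e.org/x", "rdf:type", "schema:Thing")
  expect_equal(select_profile(bare, "https://e.org/x", list(p2, p1))$name, "Alpha")
})

test_that("validation separates violations from warnings deterministically", {
  gene <- gene_profile()
  shape <- generate_shape(gene)
  complete <- conformant_entity(gene)
  rep <- validate_shape(complete, shape)
  expect_true(attr(rep, "conforms"))
  expect_equal(nrow(rep), 0)

  partial <- rdf_graph(
    subject = rep("https://e.org/g", 3),
    predicate = c("rdf:type", "schema:identifier", "schema:name"),
    object = c("schema:Gene", "ID1", "N1"),
    object_kind = c("iri", "literal", "literal")
  )
  rep2 <- validate_shape(partial, shape)
  expect_true(attr(rep2, "conforms"))
  expect_equal(attr(rep2, "n_violations"), 0)
  expect_equal(attr(rep2, "n_warnings"), 2)
  expect_setequal(rep2$property, c(
    "https://schema.org/description", "https://schema.org/url"
  ))

  missing_name <- partial[partial$object != "N1", ]
  rep3 <- validate_shape(as_rdf_graph(missing_name), shape)
  expect_false(attr(rep3, "conforms"))
  viol <- rep3[rep3$severity == "Violation", ]
  expect_equal(nrow(viol), 1)
  expect_equal(viol$property, "https://schema.org/name")
})

test_that("removal law: dropping one property yields exactly one finding", {
  for (prof in list(gene_profile(), tool_profile())) {
    shape <- generate_shape(prof)
    full <- conformant_entity(prof)
    stopifnot(attr(validate_shape(full, shape), "conforms"))
    for (p in prof$minimum_properties) {
      cut <- as_rdf_graph(full[full$predicate != p, ])
      rep <- validate_shape(cut, shape)
      viol <- rep[rep$severity == "Violation", ]
      expect_equal(nrow(viol), 1, label = paste(prof$name, p))
      expect_equal(viol$property, p)
    }
    for (p in prof$recommended_properties) {
      cut <- as_rdf_graph(full[full$predicate != p, ])
      rep <- validate_shape(cut, shape)
      warn <- rep[rep$severity == "Warning", ]
      expect_equal(nrow(warn), 1, label = paste(prof$name, p))
      expect_equal(warn$property, p)
      expect_equal(attr(rep, "n_violations"), 0)
    }
  }
})

test_that("adding triples never increases violation or warning counts", {
  gene <- gene_profile()
  shape <- generate_shape(gene)
  partial <- rdf_graph(
    subject = rep("https://e.org/g", 2),
    predicate = c("rdf:type", "schema:identifier"),
    object = c("schema:Gene", "ID1"),
    object_kind = c("iri", "literal")
  )
  base <- validate_shape(partial, shape)
  for (i in 1:40) {
    extra <- random_known_triples(4, seed = 40 + i)
    extra$subject <- "https://e.org/g"
    grown <- validate_shape(graph_union(partial, as_rdf_graph(extra)), shape)
    expect_lte(attr(grown, "n_violations"), attr(base, "n_violations"))
    expect_lte(attr(grown, "n_warnings"), attr(base, "n_warnings"))
  }
})

test_that("humanized messages phrase violations and warnings correctly", {
  gene <- gene_profile()
  shape <- generate_shape(gene)
  g <- rdf_graph(
    subject = rep("https://e.org/g", 2),
    predicate = c("rdf:type", "schema:identifier"),
    object = c("schema:Gene", "ID1"),
    object_kind = c("iri", "literal")
  )
  msgs <- humanize(validate_shape(g, shape))
  expect_length(msgs, 3)
  must <- msgs[grepl("must be", msgs)]
  should <- msgs[grepl("should be", msgs)]
  expect_length(must, 1)
  expect_match(must, "schema:name")
  expect_length(should, 2)
  expect_true(all(grepl("https://e.org/g", msgs)))
  expect_length(humanize(validate_shape(conformant_entity(gene), shape)), 0)
})

test_that("completeness equals one minus the warning fraction", {
  gene <- gene_profile()
  shape <- generate_shape(gene)
  g <- rdf_graph(
    subject = rep("https://e.org/g", 3),
    predicate = c("rdf:type", "schema:identifier", "schema:name"),
    object = c("schema:Gene", "ID1", "N"),
    object_kind = c("iri", "literal", "literal")
  )
  rep <- validate_shape(g, shape)
  cf <- completeness(rep, gene)
  expect_equal(as.numeric(cf), 1 - attr(rep, "n_warnings") / length(gene$recommended_properties))
})
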