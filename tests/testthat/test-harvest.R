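test_that("pages without annotation markup extract to the empty graph", {
  ex <- extract_embedded(make_bare_page(), "https://ex.org/bare")
  expect_equal(n_triples(ex$graph), 0)
  expect_length(ex$syntaxes_found, 0)
})

test_that("a JSON-LD block with three statements yields three triples", {
  # independently countable: three key/value statements on one node
  html <- '<html><head><script type="application/ld+json">
  {"@context": {"schema": "https://schema.org/"},
   "@id": "https://ex.org/d",
   "schema:name": "d", "schema:description": "x", "schema:version": "1"}
  </script></head><body></body></html>'
  ex <- extract_embedded(html, "https://ex.org/d")
  expect_equal(n_triples(ex$graph), 3)
  expect_equal(ex$syntaxes_found, "json-ld")
})

test_that("identical assertions across syntaxes are deduplicated", {
  html <- '<html><head><script type="application/ld+json">
  {"@context": {"schema": "https://schema.org/"},
   "@id": "https://ex.org/d", "schema:name": "x"}
  </script></head>
  <body><div prefix="schema: https://schema.org/" about="https://ex.org/d">
  <span property="schema:name">x</span></div></body></html>'
  ex <- extract_embedded(html, "https://ex.org/d")
  expect_equal(n_triples(ex$graph), 1)
  expect_setequal(ex$syntaxes_found, c("json-ld", "rdfa"))
})

test_that("extraction of two blocks equals the union of block extractions", {
  block <- function(id, name) {
    sprintf(
      '<script type="application/ld+json">{"@context":{"schema":"https://schema.org/"},"@id":"%s","schema:name":"%s"}</script>',
      id, name
    )
  }
  a <- block("https://ex.org/a", "A")
  b <- block("https://ex.org/b", "B")
  wrap <- function(x) paste0("<html><head>", x, "</head><body></body></html>")
  both <- extract_embedded(wrap(paste0(a, b)), "https://ex.org/")$graph
  ga <- extract_embedded(wrap(a), "https://ex.org/")$graph
  gb <- extract_embedded(wrap(b), "https://ex.org/")$graph
  expect_true(graphs_equal(both, graph_union(ga, gb)))
})

test_that("extraction is idempotent and deterministic", {
  html <- make_computational_tool_page(page_recipe())
  e1 <- extract_embedded(html, "https://ex.org/t")
  e2 <- extract_embedded(html, "https://ex.org/t")
  expect_true(graphs_equal(e1$graph, e2$graph))
  expect_identical(e1$syntaxes_found, e2$syntaxes_found)
})

test_that("a malformed JSON-LD block is skipped, others still parse", {
  html <- '<html><head>
  <script type="application/ld+json">{not json at all</script>
  <script type="application/ld+json">
  {"@context":{"schema":"https://schema.org/"},"@id":"https://ex.org/d","schema:name":"ok"}
  </script></head><body></body></html>'
  expect_warning(
    ex <- extract_embedded(html, "https://ex.org/d"),
    "malformed JSON-LD"
  )
  expect_equal(n_triples(ex$graph), 1)
})

test_that("relative references resolve against the declared or final base", {
  html <- '<html><head><base href="https://declared.org/dir/">
  <script type="application/ld+json">
  {"@context":{"schema":"https://schema.org/"},"@id":"item","schema:name":"x"}
  </script></head></html>'
  ex <- extract_embedded(html, "https://fetched.org/")
  expect_equal(ex$graph$subject, "https://declared.org/dir/item")
})

test_that("make_resource enforces the subject invariant", {
  r <- make_resource("https://ex.org/a", rdf_graph("https://ex.org/a", "schema:name", "x"))
  expect_equal(n_triples(r$graph), 1)
  expect_error(
    make_resource("relative/path"),
    class = "faircheckr_invariant_error"
  )
  empty <- make_resource("https://ex.org/bare")
  expect_equal(n_triples(empty$graph), 0)
})

test_that("round trip: generated pages extract to exactly the recipe triples", {
  u <- "https://tools.example.org/phyml"
  expected <- faircheckr:::recipe_triples(page_recipe(), u)
  for (syn in c("json-ld", "rdfa", "microdata")) {
    html <- make_computational_tool_page(page_recipe(syntax = syn))
    got <- extract_embedded(html, u)$graph
    expect_true(graphs_equal(got, expected), label = paste("syntax", syn))
  }
})

test_that("dump partitioning matches the brute-force reachability oracle", {
  ttl <- '
@prefix schema: <https://schema.org/> .
<https://ex.org/t1> a schema:SoftwareApplication ;
    schema:name "one" ; schema:author <https://ex.org/p1> ;
    schema:url "u1" .
<https://ex.org/p1> schema:name "alice" .
<https://ex.org/t2> a schema:SoftwareApplication ;
    schema:name "two" ; schema:version "2" ;
    schema:description "d2" .
'
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(ttl, path)
  parts <- load_dump(path, "turtle")
  expect_length(parts, 2)
  expect_setequal(names(parts), c("https://ex.org/t1", "https://ex.org/t2"))
  expect_equal(n_triples(parts[["https://ex.org/t2"]]), 4)
  # nested node triples assigned to the root that links them
  full <- read_rdf(path, "turtle")
  oracle <- oracle_reachable_triples(full, "https://ex.org/t1", depth = 3)
  expect_true(graphs_equal(parts[["https://ex.org/t1"]], oracle))
  expect_true(any(parts[["https://ex.org/t1"]]$object == "alice"))
})

test_that("an empty dump partitions to an empty mapping", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines("", path)
  expect_length(load_dump(path, "turtle"), 0)
})

test_that("partition depth bound prevents unbounded graph bleed", {
  # chain r -> n1 -> n2 -> n3 -> n4: depth 3 keeps n4's own triples out
  g <- as_rdf_graph(tibble::tibble(
    subject = c("https://ex.org/r", "https://ex.org/r", "https://ex.org/n1",
                "https://ex.org/n2", "https://ex.org/n3", "https://ex.org/n4"),
    predicate = c(
      faircheckr:::RDF_TYPE,
      rep("https://schema.org/about", 5)
    ),
    object = c("https://schema.org/Dataset", "https://ex.org/n1",
               "https://ex.org/n2", "https://ex.org/n3", "https://ex.org/n4",
               "https://ex.org/n5"),
    object_kind = "iri", lang = NA_character_, datatype = NA_character_
  ))
  path <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(g, path)
  parts <- load_dump(path, "turtle")
  sub <- parts[["https://ex.org/r"]]
  expect_true("https://ex.org/n2" %in% sub$subject)
  expect_false("https://ex.org/n4" %in% sub$subject)
})

test_that("fetch records status, follows redirects, reads local files", {
  pages <- c(
    bare.html = make_bare_page()
  )
  with_fixture_server(pages, function(base) {
    ok <- fetch(paste0(base, "bare.html"))
    expect_equal(ok$status, 200L)
    expect_match(ok$body, "PhyML")

    nf <- fetch(paste0(base, "nope.html"))
    expect_equal(nf$status, 404L)

    rd <- fetch(paste0(base, "redirect/bare.html"))
    expect_equal(rd$status, 200L)
    expect_equal(rd$redirects, 1L)
    expect_equal(rd$final_url, paste0(base, "bare.html"))
  })

  path <- withr::local_tempfile(fileext = ".html")
  writeLines(make_bare_page(), path, sep = "")
  lf <- fetch(path)
  expect_true(is.na(lf$status))
  expect_match(lf$body, "PhyML")
  expect_error(fetch("/no/such/file.html"), class = "faircheckr_fetch_error")
})

test_that("render_js without a renderer warns and keeps the static body", {
  path <- withr::local_tempfile(fileext = ".html")
  writeLines(make_bare_page(), path, sep = "")
  expect_warning(f <- fetch(path, render_js = TRUE), "renderer")
  expect_false(f$render_js_used)
  rendered <- fetch(path, render_js = TRUE, renderer = function(b) paste0(b, "<!--r-->"))
  expect_true(rendered$render_js_used)
  expect_match(rendered$body, "<!--r-->")
})
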