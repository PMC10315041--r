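offline_cfg <- fair_config()

test_that("the registry holds exactly the twelve canonical metrics", {
  reg <- metric_registry()
  expect_equal(reg$metric_id, faircheckr:::METRIC_IDS)
  expect_false(any(duplicated(reg$metric_id)))
  pp <- reg[reg$test_kind == "property_presence", ]
  expect_true(all(lengths(pp$target_properties) > 0))
})

test_that("property-presence metrics pass with evidence, fail without", {
  reg <- metric_registry()
  r11 <- reg[reg$metric_id == "R1.1", ]
  res <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "schema:license", "MIT")
  )
  out <- evaluate_metric(res, r11, offline_cfg)
  expect_equal(out$status, "pass")
  expect_equal(out$n_evidence, 1)

  res2 <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "schema:name", "x")
  )
  expect_equal(evaluate_metric(res2, r11, offline_cfg)$status, "fail")

  r12 <- reg[reg$metric_id == "R1.2", ]
  res3 <- make_resource("https://ex.org/t", graph_union(
    rdf_graph("https://ex.org/t", "prov:wasGeneratedBy", "https://ex.org/act"),
    rdf_graph("https://ex.org/t", "pav:authoredBy", "https://ex.org/p")
  ))
  out3 <- evaluate_metric(res3, r12, offline_cfg)
  expect_equal(out3$status, "pass")
  expect_equal(out3$n_evidence, 2)
})

test_that("every property-presence metric equals the scan oracle on random cases", {
  reg <- metric_registry()
  pp <- reg[reg$test_kind == "property_presence", ]
  for (i in 1:100) {
    g <- random_graph(max_triples = 50, seed = 5000 + i)
    # non-persistent subject so the F1B scheme disjunct stays false
    res <- make_resource("https://data.example.org/r1", g)
    for (j in seq_len(nrow(pp))) {
      out <- evaluate_metric(res, pp[j, ], offline_cfg)
      expect_equal(
        out$status == "pass",
        oracle_any_property(g, pp$target_properties[[j]]),
        label = paste("case", i, pp$metric_id[j])
      )
    }
  }
})

test_that("F1B accepts either an identifier property or a persistent URL", {
  f1b <- metric_registry()[metric_registry()$metric_id == "F1B", ]
  with_prop <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "schema:identifier", "XYZ-1")
  )
  expect_equal(evaluate_metric(with_prop, f1b, offline_cfg)$status, "pass")
  doi_url <- make_resource("https://doi.org/10.5281/zenodo.1", empty_graph())
  expect_equal(evaluate_metric(doi_url, f1b, offline_cfg)$status, "pass")
  neither <- make_resource("https://ex.org/t", empty_graph())
  expect_equal(evaluate_metric(neither, f1b, offline_cfg)$status, "fail")
})

test_that("A1.1 needs an open protocol and a resolving target", {
  a11 <- metric_registry()[metric_registry()$metric_id == "A1.1", ]
  ok <- make_resource("https://ex.org/t", empty_graph(), http_status = 200L)
  expect_equal(evaluate_metric(ok, a11, offline_cfg)$status, "pass")
  err <- make_resource("https://ex.org/t", empty_graph(), http_status = 404L)
  expect_equal(evaluate_metric(err, a11, offline_cfg)$status, "fail")
  urn <- make_resource("urn:uuid:1", empty_graph(), http_status = 200L)
  expect_equal(evaluate_metric(urn, a11, offline_cfg)$status, "fail")
  dump <- make_resource("https://ex.org/t", rdf_graph("https://ex.org/t", "schema:name", "x"),
    content_kind = "rdf_serialization"
  )
  expect_equal(evaluate_metric(dump, a11, offline_cfg)$status, "pass")
})

test_that("I3 requires an external, non-type IRI object", {
  i3 <- metric_registry()[metric_registry()$metric_id == "I3", ]
  same_auth <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "schema:url", "https://ex.org/t/home")
  )
  expect_equal(evaluate_metric(same_auth, i3, offline_cfg)$status, "fail")
  only_type <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "rdf:type", "schema:Dataset")
  )
  expect_equal(evaluate_metric(only_type, i3, offline_cfg)$status, "fail")
  external <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "schema:citation", "https://doi.org/10.1/x")
  )
  expect_equal(evaluate_metric(external, i3, offline_cfg)$status, "pass")
})

test_that("I2 demands every used namespace be registered", {
  i2 <- metric_registry()[metric_registry()$metric_id == "I2", ]
  good <- make_resource(
    "https://ex.org/t",
    rdf_graph("https://ex.org/t", "schema:name", "x")
  )
  expect_equal(evaluate_metric(good, i2, offline_cfg)$status, "pass")
  mixed <- make_resource("https://ex.org/t", graph_union(
    rdf_graph("https://ex.org/t", "schema:name", "x"),
    rdf_graph("https://ex.org/t", "http://unknown.example/ns#p", "y")
  ))
  expect_equal(evaluate_metric(mixed, i2, offline_cfg)$status, "fail")
  expect_equal(
    evaluate_metric(make_resource("https://ex.org/t"), i2, offline_cfg)$status,
    "fail"
  )
})

test_that("evaluate_all reproduces the two worked page examples", {
  bare <- page_resource(make_bare_page())
  r <- evaluate_all(bare, offline_cfg)
  expect_equal(r$metric_id, faircheckr:::METRIC_IDS)
  expect_equal(r$metric_id[r$status == "pass"], c("F1A", "A1.1"))

  tool <- page_resource(make_computational_tool_page())
  r2 <- evaluate_all(tool, offline_cfg)
  expect_equal(sum(r2$status == "pass"), 10)
  expect_equal(r2$metric_id[r2$status != "pass"], c("R1.1", "R1.2"))

  # adding the license group flips R1.1 only
  licensed <- page_resource(make_computational_tool_page(page_recipe(
    include_groups = c(
      "findability_ids", "accessibility", "license",
      "profile_minimum", "profile_recommended", "edam_terms"
    )
  )))
  r3 <- evaluate_all(licensed, offline_cfg)
  expect_equal(r3$metric_id[r3$status != "pass"], "R1.2")
})

test_that("an empty graph behind a dead URL fails all twelve metrics", {
  dead <- make_resource("not a uri", empty_graph(), strict = FALSE)
  r <- evaluate_all(dead, offline_cfg)
  expect_true(all(r$status == "fail"))
})

test_that("alternative implementations are selectable per metric id", {
  register_metric_impl("R1.1", "strict", function(resource, definition, config) {
    faircheckr:::metric_result_row("R1.1", "fail", log = "strict mode")
  })
  tool <- page_resource(make_computational_tool_page(page_recipe(
    include_groups = c("profile_minimum", "license")
  )))
  default_run <- evaluate_all(tool, offline_cfg)
  expect_equal(default_run$status[default_run$metric_id == "R1.1"], "pass")
  strict_cfg <- fair_config(implementations = c("R1.1" = "strict"))
  strict_run <- evaluate_all(tool, strict_cfg)
  expect_equal(strict_run$status[strict_run$metric_id == "R1.1"], "fail")
  # only R1.1 differs
  expect_equal(
    default_run$status[default_run$metric_id != "R1.1"],
    strict_run$status[strict_run$metric_id != "R1.1"]
  )
  expect_error(
    register_metric_impl("F9", "x", function(...) NULL),
    class = "faircheckr_contract_error"
  )
})

test_that("one failing metric implementation never blocks the others", {
  register_metric_impl("I3", "broken", function(resource, definition, config) {
    stop("backend down")
  })
  cfg <- fair_config(implementations = c("I3" = "broken"))
  r <- evaluate_all(page_resource(make_computational_tool_page()), cfg)
  expect_equal(r$status[r$metric_id == "I3"], "error")
  expect_equal(sum(r$status == "pass"), 9)
  expect_match(r$log[r$metric_id == "I3"], "backend down")
})

test_that("metrics are monotone under registered-vocabulary augmentation", {
  base <- page_resource(make_computational_tool_page())
  before <- evaluate_all(base, offline_cfg)
  for (i in 1:30) {
    aug <- base
    aug$graph <- graph_union(aug$graph, random_known_triples(5, seed = i))
    after <- evaluate_all(aug, offline_cfg)
    flipped <- before$status == "pass" & after$status != "pass"
    expect_false(any(flipped), label = paste("augmentation", i))
  }
})

test_that("enrichment can only grow the pass set", {
  dir <- withr::local_tempdir()
  wd <- default_endpoints()["wikidata"]
  res <- page_resource(make_computational_tool_page())
  q <- build_describe("https://doi.org/10.5281/zenodo.7654321", wd$wikidata)
  write_fixture_response(dir, q, graph_union(
    rdf_graph(res$subject_url, "schema:license", "https://opensource.org/licenses/MIT"),
    rdf_graph(res$subject_url, "schema:author", "G")
  ))
  plain_cfg <- fair_config()
  enriched_cfg <- fair_config(
    enrichment = TRUE, endpoints = wd,
    transport = fixture_transport(dir)
  )
  plain <- evaluate_all(res, plain_cfg)
  enriched <- evaluate_all(res, enriched_cfg)
  expect_true(all(
    enriched$status[plain$status == "pass"] == "pass"
  ))
  expect_equal(sum(enriched$status == "pass"), 12)
})

test_that("offline evaluation reports are byte-identical across runs", {
  res <- page_resource(make_computational_tool_page())
  a <- export_report(evaluate_all(res, offline_cfg), "json")
  b <- export_report(evaluate_all(res, offline_cfg), "json")
  expect_identical(a, b)
})
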