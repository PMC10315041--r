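test_that("combination counts partition resources exactly", {
  v <- all_pass_vector()
  same3 <- list(a = v, b = v, c = v)
  out <- summarize_combinations(same3)
  expect_equal(nrow(out), 1)
  expect_equal(out$n, 3)
  expect_equal(out$combination, paste(faircheckr:::METRIC_IDS, collapse = "+"))

  mixed <- list(a = v, b = vec_with("R1.1"), c = vec_with("R1.1"), d = vec_with("R1.1", "R1.2"))
  out2 <- summarize_combinations(mixed)
  expect_equal(sum(out2$n), 4)
  expect_equal(nrow(out2), 3)
  expect_equal(max(out2$n), 2)

  expect_equal(nrow(summarize_combinations(list())), 0)
  expect_error(
    summarize_combinations(list(a = c(TRUE, FALSE), b = TRUE)),
    class = "faircheckr_contract_error"
  )
})

test_that("completeness handles full, empty and degenerate profiles", {
  p <- profile_spec("P", "https://p.org/p", "schema:Thing",
    minimum_properties = "schema:name",
    recommended_properties = paste0("schema:r", 1:6)
  )
  fake_report <- function(nw) {
    structure(tibble::tibble(severity = rep("Warning", nw)),
      n_warnings = nw, class = c("shape_report", class(tibble::tibble()))
    )
  }
  expect_equal(as.numeric(completeness(fake_report(3), p)), 0.5)
  expect_equal(as.numeric(completeness(fake_report(0), p)), 1.0)
  expect_equal(as.numeric(completeness(fake_report(6), p)), 0.0)
  norec <- profile_spec("Q", "https://p.org/q", "schema:Thing",
    minimum_properties = "schema:name"
  )
  cf <- completeness(fake_report(0), norec)
  expect_equal(as.numeric(cf), 1.0)
  expect_true(attr(cf, "no_recommended"))
})

test_that("recommendations guide failures and stay silent on passes", {
  lic <- recommendation_for("R1.1", "fail")
  for (prop in c("schema:license", "dct:license", "doap:license", "dbpedia-owl:license", "cc:license")) {
    expect_match(lic$text, prop, fixed = TRUE)
  }
  expect_equal(recommendation_for("F1A", "pass")$text, "")
  f2a <- recommendation_for("F2A", "fail")
  expect_match(f2a$text, "Search Engine Optimisation")
  expect_equal(f2a$links, "fair-cookbook-recipe-8")
  f1b <- recommendation_for("F1B", "fail")
  expect_match(f1b$text, "persistent identifier")
  expect_equal(f1b$links, "fair-cookbook-recipe-1")
  expect_equal(recommendation_for("F2B", "fail")$links,
               c("fair-cookbook-recipe-3", "fair-cookbook-recipe-4"))
  expect_error(recommendation_for("F9", "fail"), class = "faircheckr_contract_error")
})

test_that("exports carry one row per metric and round-trip vectors", {
  res <- page_resource(make_computational_tool_page())
  r <- evaluate_all(res)
  csv <- export_report(r, "csv")
  parsed <- readr::read_csv(I(csv), show_col_types = FALSE)
  expect_equal(nrow(parsed), 12)
  expect_equal(parsed$metric_id, faircheckr:::METRIC_IDS)

  md <- export_report(r, "markdown")
  expect_match(md, "\\| *R1.1 *\\| *fail")
  expect_error(export_report(r, "yaml"), class = "faircheckr_contract_error")

  summary <- batch_summary(list(a = r, b = r))
  json <- export_report(summary, "json")
  back <- jsonlite::fromJSON(json)
  expect_equal(back$n_resources, 2)
  expect_equal(back$n_evaluations, 24)
  mat <- membership_matrix(summary)
  expect_equal(back$matrix$R1.1, mat$R1.1)
  expect_equal(unname(unlist(back$matrix[1, faircheckr:::METRIC_IDS])),
               unname(as.integer(r$status == "pass")))

  empty <- batch_summary(list())
  expect_equal(empty$n_resources, 0)
  csv_empty <- export_report(empty, "csv")
  expect_match(strsplit(csv_empty, "\n")[[1]][1], "resource")
})

test_that("batch invariants hold on generated batches", {
  b <- make_batch(12,
    vectors = list(all_pass_vector(), vec_with("R1.1"), vec_with("R1.1", "R1.2", "I3")),
    k_recommended = c(2, 5, 7), seed = 3
  )
  s <- run_batch(b$path, config = batch_config(), profile = "ComputationalTool")
  expect_equal(s$n_resources, 12)
  expect_equal(s$n_evaluations, 12 * 12)
  expect_equal(sum(s$combination_counts$n), 12)
  # ledger multiset equals the summarized combinations
  ledger_combos <- summarize_combinations(b$ledger[, c("resource", faircheckr:::METRIC_IDS)])
  expect_equal(s$combination_counts, ledger_combos)
  # prescribed completeness: mean over resources of k/7
  expect_equal(s$mean_completeness, mean(c(2, 5, 7) / 7))
  g <- glance(s)
  expect_equal(g$n_resources, 12)
  t <- tidy(s)
  expect_equal(nrow(t), 144)
})

test_that("batch pass-rates recover prescribed probabilities", {
  p <- setNames(rep(0.8, 12), faircheckr:::METRIC_IDS)
  p[["R1.1"]] <- 0.3
  b <- make_batch(300, pass_probabilities = p, seed = 11)
  led <- b$ledger
  # R1.1 draw is conditioned only on F2B (p = .8): expected rate .8 * .3
  n <- nrow(led)
  for (m in c("R1.1", "F1B", "A1.2")) {
    expected <- 0.8 * p[[m]]
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(led[[m]]) - expected), 3 * se + 1e-9, label = m)
  }
  expect_true(all(led$F2A), label = "F2A always realizable in dumps")
})

test_that("plots build from result and batch objects", {
  r <- evaluate_all(page_resource(make_bare_page()))
  pl <- ggplot2::ggplot_build(autoplot(r))
  expect_gt(nrow(pl$data[[1]]), 0)
  b <- make_batch(4, vectors = list(all_pass_vector(), vec_with("R1.1")), seed = 2)
  s <- run_batch(b$path, config = batch_config())
  pl2 <- ggplot2::ggplot_build(autoplot(s))
  expect_equal(sum(pl2$data[[1]]$x), 4)
})
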