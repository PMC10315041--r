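Package: faircheckr
Title: Automated FAIR Maturity Assessment of Web Resource Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harvests structured metadata embedded in web pages (JSON-LD,
    RDFa, HTML microdata) or supplied as RDF dumps, evaluates FAIR maturity
    metrics with SPARQL ASK queries generated over curated property sets,
    optionally enriches metadata from public knowledge graphs via DESCRIBE
    queries, validates metadata completeness against community profiles
    through generated SHACL shapes, and reports results with actionable
    recommendations, both for single resources and in batch. Results are
    tidy tibbles throughout, with tidy()/glance()/autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    curl,
    digest,
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    callr,
    httpuv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
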