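# faircheckr

Automated FAIR maturity assessment of the metadata that life-science web
resources — datasets, bioinformatics tools, training materials — embed in
their pages or publish as RDF.

## The problem

Whether a digital resource is Findable, Accessible, Interoperable and
Reusable is, in practice, a property of its *metadata*: does the page carry
machine-readable statements, do they use shared vocabularies, do they name
a license, provenance, a persistent identifier? Checking this by hand
requires semantic-web expertise most data producers and tool developers do
not have. `faircheckr` automates the check and — unlike a bare score —
tells the user *what to add* to improve.

The package:

1. **harvests** structured annotations embedded in a web page (JSON-LD
   script blocks, RDFa attributes, HTML microdata) or loads an RDF dump,
   into one deduplicated triple set per resource;
2. **evaluates twelve FAIR maturity metrics** (F1A, F1B, F2A, F2B, A1.1,
   A1.2, I1, I2, I3, R1.1, R1.2, R1.3). Property-based metrics are run as
   generated SPARQL ASK queries: one shared template whose `VALUES ?p
   { ... }` clause enumerates a curated target-property list per metric
   (license properties for R1.1, provenance vocabularies PROV/PAV/DC for
   R1.2, access-policy properties for A1.2, identifier properties for
   F1B), answering true iff some triple's predicate is in the list:

   ```sparql
   ASK {
       VALUES ?p { <https://schema.org/license> <http://purl.org/dc/terms/license> }
       ?s ?p ?o .
   }
   ```

3. optionally **enriches** the graph from public knowledge graphs
   (Wikidata via the DOI cross-reference property P356, OpenAIRE,
   OpenCitations) with generated SPARQL DESCRIBE queries, behind a
   pluggable, cacheable, offline-mockable transport;
4. **validates completeness** against community metadata profiles
   (Bioschemas-style): a profile's *minimum* properties become SHACL
   property shapes with `sh:Violation` severity, *recommended* properties
   become `sh:Warning` shapes, all generated from a single template and
   reported as requirements ("must be") and improvements ("should be");
5. **aggregates batches** into exact metric-combination counts (UpSet-plot
   input) and profile-completeness statistics, with JSON/CSV/markdown
   export, `tidy()`/`glance()` methods and `autoplot()`.

Everything runs offline by default: vocabulary registries are local
catalog snapshots, enrichment endpoints are fixture transports, and a
synthetic-data module generates pages, dumps and profiles with known
ground truth. Live registries and endpoints are opt-in.

## Worked example

Serve a fully annotated software-tool page (all profile minimum and
recommended properties, an identifier, EDAM term references, a download
URL — but no license and no provenance) and check it:

```r
library(faircheckr)

with_fixture_server(
  c(tool.html = make_computational_tool_page()),
  function(base) {
    res <- run_check(paste0(base, "tool.html"))
    print(glance(res$results))
    print(tidy(res$results)[, c("metric_id", "status", "n_evidence")], n = 12)
  }
)
#> # A tibble: 1 × 5
#>   resource                         n_metrics n_pass n_fail n_error
#>   <chr>                                <int>  <int>  <int>   <int>
#> 1 http://127.0.0.1:45001/tool.html        12     10      2       0
#> # A tibble: 12 × 3
#>    metric_id status n_evidence
#>    <chr>     <chr>       <int>
#>  1 F1A       pass            1
#>  2 F1B       pass            1
#>  3 F2A       pass           15
#>  4 F2B       pass           13
#>  5 A1.1      pass            2
#>  6 A1.2      pass            1
#>  7 I1        pass           15
#>  8 I2        pass            1
#>  9 I3        pass            7
#> 10 R1.1      fail            0
#> 11 R1.2      fail            0
#> 12 R1.3      pass            1
```

Ten of twelve metrics pass; the two failures (license R1.1, provenance
R1.2) come back with recommendations naming the exact properties to add
(`schema:license`, `dct:license`, ... / `prov:*`, `pav:*`,
`dct:creator`, ...). The same page without any embedded metadata passes
only F1A and A1.1 — a resolvable URL over an open protocol is all a bare
page has to offer.

The "inspect" facet validates against a community profile:

```r
ins <- run_inspect("tool.html")        # selected by rdf:type -> ComputationalTool
glance(ins$report)                     # conforms = TRUE, 0 violations, 0 warnings
ins$completeness                       # 1 (all recommended properties present)
```

For a gene page carrying only `schema:identifier` and `schema:name`, the
Gene profile reports zero violations and two warnings, humanized as
"... property schema:description should be provided." — minimum
properties missing would instead be phrased "must be provided."

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/fairchecker.R check  page.html --format json
Rscript inst/cli/fairchecker.R inspect page.html --profile auto --emit-shapes shapes/
Rscript inst/cli/fairchecker.R batch  dump.ttl --out summary.json --membership-matrix m.csv
```

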