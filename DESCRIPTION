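Package: taxolink
Title: Link Taxonomic Name Identifiers to the Published Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connecting persistent identifiers for taxonomic names
    (Life Science Identifiers, LSIDs) to work-level bibliographic identifiers
    (DOIs, Wikidata items, Handles and others). Parses the page-level
    "microcitations" used by nomenclators such as Index Fungorum and IPNI,
    resolves them against a page-range-indexed bibliography with article-number
    and fuzzy full-citation fallbacks, flags likely journal/volume errors in
    source records, exports the resulting mapping as a Catalogue of Life Data
    Package (CoLDP) checklist and as schema.org N-Triples, assembles a small
    names-publications-people knowledge graph from ORCID-style person records,
    and computes coverage statistics (identifier counts per source,
    decade-by-venue name densities, long-tail curves). A seeded synthetic
    corpus generator with ground-truth links and a corruption model makes every
    stage testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
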