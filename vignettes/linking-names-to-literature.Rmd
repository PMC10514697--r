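---
title: "Linking taxonomic names to the literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking taxonomic names to the literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxolink)
```

## The resolution problem

A nomenclator record ties a name's LSID to a *microcitation* — a pointer to
the page on which the name was published, such as
`"Hu, Dai, ... & Zhang, IMA Fungus 83: 166 (2021)"` — rather than to the
work. The work, if it is modern, has a DOI; older works may have JSTOR,
BioStor, Biodiversity Heritage Library, Handle or plain URL identifiers,
and many have Wikidata items. The task is to recover, for each LSID, the
work-level identifiers of the publication the microcitation points into.

Given a bibliography that records each work's container (journal,
monograph series or book), volume, page range and year, resolution is in
principle simple: find the article in the cited volume whose page range
contains the cited page. Everything else in the match engine exists because
real data violate the preconditions of that sentence — page ranges are
missing from much article metadata, journals switch to continuous article
numbering where every article starts on page 1, publication years drift
from issue years, containers are cited under abbreviated aliases, and some
source records are simply wrong.

## The microcitation grammar

`parse_microcitation()` applies an ordered alternation of three patterns,
first match wins:

1. `[authors,] <container> <volume> [(<issue>)]: <page> (<year>)` — the
   nomenclator house style. Any text before the container match is kept as
   the author block; the container token cannot contain commas or digits,
   which is what separates it from the author list.
2. `<container>, volume <v>, issue no. <n>` — the style used for
   continuous-article-number journals; `n` becomes `article_number`.
3. `[authors,] <container> <volume> (<issue>): <page>` — the year-less
   variant.

Page and article number are mutually exclusive in one parse result. Page
tokens that are not plain arabic numerals — roman-numeral front matter,
plate references — leave `page` unset rather than being guessed at;
a wrong page is worse than no page, because a wrong page can produce a
confident wrong match. The raw string is preserved verbatim in every
result, and failures either raise a typed condition or (inside the
pipeline) become `unmatched` entries.

Container names are normalized through an alias table
(`"Front. Microbiol."` → `"Frontiers in Microbiology"`), matched case- and
punctuation-insensitively; unknown containers are title-cased. The
operation is idempotent, which the tests check, because it is applied both
at index-build time and at parse time and must agree with itself.

## The evidence cascade

`resolve_microcitation()` tries, in order, and stops at the first success:

1. **Page range.** Under the `(canonical container, volume)` key, accept
   works whose `[page_start, page_end]` contains the cited page and whose
   year is within ±1 of the cited year. The ±1 window absorbs
   publication-date versus issue-date drift, a familiar nomenclatural
   problem; it is configurable (`year_window`). Ties — overlapping ranges
   both containing the page — are flagged `ambiguous` and broken by
   narrowest range first (a short treatment containing the page is more
   specific than a long monograph), then exact `page_start` equality, then
   lowest `work_id` for determinism.
2. **Article number.** A work under the same canonical container matches
   when its stored article number, or the final dot-/slash-delimited token
   of its DOI, equals the citation's article number. This exploits
   non-opaque DOIs: `"issue no. 737541"` and DOI
   `10.3389/fmicb.2021.737541` share their tail. Volume disagreement does
   not block the match but is flagged.
3. **Full citation.** A weighted similarity over all works: container
   equality 0.4, exact volume 0.2, year within the window 0.2, author-token
   Jaccard overlap 0.2; accept the best score at or above the threshold
   (default 0.8, configurable, as are the weights). With these defaults a
   record must agree on the container plus two of the remaining three
   fields to be accepted; container agreement alone (0.4) never suffices.
   Raising the threshold can only lose matches, a monotonicity property the
   tests assert.

Keys under which at least `continuous_k` (default 5) works share
`page_start == 1` are treated as continuous-numbering: page containment is
meaningless there and the page-range path is disabled for that key, forcing
the article-number path.

### Mismatch diagnosis

Records that fail every path go to `detect_mismatch()`. A mismatch between
journal and volume numbers is often a clue that the source record is in
error, so the detector searches *all* containers for works with the same
volume token whose page range contains the cited page (year within the
window). Exactly one qualifying alternative container produces flags
`journal_volume_mismatch` and `suggested_alternative` plus the suggested
work; several produce `ambiguous` and no suggestion. When the citation
carries an article number instead of a page, the same search matches
article-number tokens across containers — the package's own extension,
without which a wrong-journal error on a continuous-numbering article could
never be diagnosed, since such citations have no page to match on.
Suggestions are advisory only: the entry's method remains `unmatched`, and
accepting a suggestion is a curatorial decision, not an algorithmic one.

## Exports

**CoLDP.** The checklist package holds only names mapped to at least one
persistent identifier; unmatched names (and matches to identifier-less
works) are written to an `unmapped.tsv` sidecar for audit. Reference
identifiers follow the rule: the Wikidata QID when the work has one,
otherwise `doi-` plus the DOI with `/` and `.` replaced by `-`, otherwise
the lower-cased kind plus the sanitized value of the preferred identifier.
The column set is deliberately minimal (names: ID, scientificName, rank,
referenceID, page; references: ID, citation, DOI, link, remarks) — the
format here is a carrier for exactly this mapping, not a full checklist.
Tables are UTF-8 TSV with LF endings, rows sorted (names by LSID,
references by id), so identical inputs produce byte-identical files.

**RDF.** N-Triples output is restricted to names whose work has a DOI: the
DOI is the identifier other datasets (ORCID, Wikidata) actually contain, so
DOI-less links add nothing joinable. Each name contributes exactly three
triples — type (`schema:TaxonName`, following the Bioschemas draft), label
(`schema:name`) and link (`schema:isBasedOn` to the `https://doi.org/`
IRI). LSIDs appear as `urn:lsid:` URIs in subject position, matching the
identifiers the source databases mint. The vocabulary sits in one constants
table (`kg_vocabulary()`) so it is swappable; authorship is expressed
work-centrically, `(doi, schema:creator, person)`, which keeps the
property's domain on the creative work. Person records emit type, name, one
affiliation edge per organisation and one authorship edge per DOI;
organisation nodes are minted deterministically as
`urn:org:{scheme}:{value}` so that two people at the same organisation
share a node. Organisation *name* literals are intentionally not emitted by
`person_to_triples()` — the org node identity is its identifier, and
keeping the per-person output to the counted shape makes the triple-count
laws exact.

ORCID-sourced person data are user-supplied and messy; `clean_person_record()`
trims whitespace and control characters, repairs missing schemes
(`orcid.org/…` → `https://orcid.org/…`), normalizes DOIs, drops fields that
remain invalid, and rejects a record only when the ORCID itself is
unrecoverable. `query_org_authors()` implements the one join the graph is
built to answer — name → work → person → organisation — as a plain
relational join over the triple table, checked in tests against a
brute-force nested loop.

## Coverage statistics

`summarize_by_identifier()` counts, per source database: total names, names
with publication information, names per identifier kind (a name counts once
per kind it carries), and `Any` — names with at least one identifier, which
is not the sum of the kind rows because names carry several kinds. The
totals column is always recomputed as row sums (`counts_add_totals()`),
never stored, and `coverage_percentage()` is `100 × Any /
NamesWithPublications` on the totals.

The decade matrix bins dated names of the top-k venues into left-closed
10-year decades over a configurable window (default 1750–2020); names
outside the window go to an explicit `"other"` bucket rather than being
dropped, and undated names are excluded from the matrix (the count tables
have no year dimension, so they keep them). Venues are ordered by **modal
decade** — the decade with the most names, ties to the earlier decade and
then the larger venue — which makes venue turnover visible. The attached
PID percentage is computed **per name** (share of the venue's names mapped
to at least one identifier); per-work percentages would be a defensible
alternative, but per-name matches how the count tables are defined here.
The long-tail curve ranks venues by names published and accumulates
percentages against *all* names in the corpus, not just the displayed top,
so a short head reaching only 30–50% is visible as such.

## The synthetic corpus

`generate_corpus()` emulates the structure the matcher depends on, not the
content: journals with volumes of articles occupying contiguous,
non-overlapping page ranges (article lengths 4–30 pages), names citing a
page inside their true article, a configurable fraction of
continuous-numbering journals (default 0.1) whose articles all start on
page 1 and are cited by article number, DOIs on 90% of works
(continuous-numbering works always have one — the article number *is* the
DOI tail), Wikidata QIDs on 30%, and ORCID-style person records wired to
the generated DOIs. The default corpus is 10 journals × 5 volumes × 5
articles × 2 names = 500 names over 250 works — small enough that a
hundred corpora resolve in under two minutes, large enough that every code
path (ties, continuous numbering, missing identifiers) is exercised.

Volume numbers are globally unique across journals (journal *i* holds
volumes `(i-1)·V+1 … i·V`). This is the structure that makes wrong-journal
corruption *detectable*: the cited volume does not exist in the wrong
journal, resolution fails, and the mismatch detector finds the one journal
where volume and page do fit. Real journals of course reuse volume numbers;
where they do, a wrong-journal error whose volume and page happen to fit
the wrong journal is undetectable by any page-arithmetic method, so the
generator models the detectable case and the documentation is explicit that
recovery rates on it do not transfer to corpora with colliding volume
numbering.

The corruption model applies each error archetype independently per name by
targeted substitution in the raw citation string (so untouched names stay
byte-identical): container swapped to another journal, volume ±1, page
pushed 50–500 beyond the article's end, year ±2. A log records every
alteration. All randomness flows through one integer seed; generation and
corruption use separate derived streams so corrupting a corpus does not
perturb its generation.

What passing tests on this corpus show: the cascade, tie-breaks, flags,
exports and statistics are internally correct and agree with an independent
brute-force oracle. What they do not show: robustness to the full mess of
real nomenclator strings (multilingual containers, nested parentheses,
plate citations, OCR noise), to incomplete bibliographies, or to volume
collisions as above.

## Numerical and degenerate-input choices

- Year comparison treats a missing year on either side as compatible; a
  present-but-different year within the window is accepted and, when not
  equal, flagged `year_off_by_one`.
- All tie-breaks terminate in lexicographic `work_id` order, so every
  result is deterministic; re-running the pipeline on identical inputs
  produces byte-identical outputs (tested).
- Empty inputs produce valid empty outputs everywhere (empty index, empty
  CoLDP package with headers, empty graph), not errors.
- DOIs are case-folded to lower case for comparison and storage (the DOI
  system is case-insensitive); resolver prefixes are stripped on ingest.
- A URL ending `.pdf` (case-insensitive) is classified as a PDF link; the
  URL/PDF distinction in source data has no formal rule, so this is a
  documented guess.
- ION-style full citation strings embedded in LSID metadata get no
  dedicated grammar: the standard patterns plus the full-citation fallback
  cover them, and no distinct house style was available to codify.

## Problem sizes used in checks

The shipped checks run on: 100 corpora × 500 names for oracle agreement;
5 corpora for recovery and suggestion accuracy (≈250 wrong-journal
corruptions); one corpus for round-trip and graph checks. These sizes give
binomial confidence well inside the asserted bounds (a true suggestion
accuracy of 95% would need ~12 failures in 250 to dip below the threshold)
while keeping the whole suite within a couple of minutes.

## Known limitations

- The grammar covers the two nomenclator house styles and a year-less
  variant; it does not attempt reference-string segmentation of arbitrary
  citations.
- The fuzzy path scores structured fields, not raw strings; it will not
  rescue citations whose container has no alias entry and whose volume or
  year disagree.
- The knowledge graph implements one parameterized join, not a SPARQL
  engine; the N-Triples parser handles IRIs and plain/typed/tagged
  literals, not blank nodes.
- Identifier *resolution* (dereferencing LSIDs, DOIs, ORCIDs over the
  network) is out of scope; all inputs are local files.
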