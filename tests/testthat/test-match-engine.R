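test_that("index construction keys every work once and orders by page start", {
  works <- fixture_works()
  idx <- build_index(works)
  keys <- dplyr::distinct(idx$by_cv, container_canon, volume)
  expect_equal(nrow(keys), 3) # two Mycotaxon works share a key
  expect_equal(nrow(idx$by_cv), nrow(works))
  mt <- idx$by_cv[idx$by_cv$container_canon == "Mycotaxon", ]
  expect_equal(mt$work_id, c("mt-45-101", "mt-45-113")) # ordered by page_start
  expect_error(build_index(dplyr::bind_rows(works, works)),
               class = "taxolink_duplicate_work_id")
  empty <- build_index(works[0, ])
  expect_equal(nrow(empty$works), 0)
})

test_that("page-range resolution finds the containing article", {
  idx <- build_index(fixture_works())
  mc <- parse_microcitation("Hu, Dai, Zhao & Zhang, MycoKeys 83: 166 (2021)")
  e <- resolve_microcitation(mc, idx)
  expect_equal(e$method, "page_range")
  expect_equal(e$work_id, "mk-83-161")
  expect_equal(e$flags, "")

  # page outside every range in the key -> no page match
  miss <- resolve_microcitation(parse_microcitation("MycoKeys 83: 500 (2021)"), idx)
  expect_true(is.na(miss$work_id) | miss$method != "page_range")

  # year outside the +/-1 window blocks the page match
  off <- resolve_microcitation(parse_microcitation("MycoKeys 83: 166 (2018)"), idx)
  expect_false(identical(off$method, "page_range"))
})

test_that("overlapping ranges are flagged ambiguous and tie-break to the narrower", {
  idx <- build_index(fixture_works())
  # page 120 sits in mt-45-113 (113-129, width 16) and mt-45-101 (101-125, width 24)
  e <- resolve_microcitation(parse_microcitation("Ginns, Mycotaxon 45: 120 (1992)"), idx)
  expect_equal(e$method, "page_range")
  expect_equal(e$work_id, "mt-45-113")
  expect_true(has_flag(e, "ambiguous"))
})

test_that("article numbers match DOI tails under the same container", {
  idx <- build_index(fixture_works())
  mc <- parse_microcitation("Frontiers in Microbiology, volume 12, issue no. 737541")
  e <- match_article_number(mc, idx)
  expect_equal(e$method, "article_number")
  expect_equal(e$work_id, "fm-12-737541")

  none <- match_article_number(
    parse_microcitation("Frontiers in Microbiology, volume 12, issue no. 000000"), idx)
  expect_equal(none$method, "unmatched")
  expect_true(is.na(none$work_id))

  # two works sharing the token: container agreement then lowest id breaks the tie
  works2 <- works_tbl(
    work_id = c("a1", "a2"),
    container = c("Frontiers in Microbiology", "Frontiers in Microbiology"),
    volume = c("12", "13"), year = c(2021L, 2022L),
    identifiers = list(pid_set(doi = "10.3389/fmicb.2021.737541"),
                       pid_set(doi = "10.3389/fmicb.2022.737541"))
  )
  tie <- match_article_number(mc, build_index(works2))
  expect_equal(tie$work_id, "a1")
  expect_true(has_flag(tie, "ambiguous"))
})

test_that("full-citation scoring reproduces the weighted arithmetic", {
  works <- fixture_works()
  idx <- build_index(works)
  # identical metadata scores 1.0
  mc <- parse_microcitation("Ginns, Mycotaxon 45: 9999 (1992)") # page forces fallback
  sc <- citation_similarity(mc, idx$works)
  expect_equal(max(sc), 1.0)

  # container-only agreement scores exactly the container weight
  lonely <- parse_microcitation("Somebody, Mycotaxon 99: 1 (1900)")
  sc2 <- citation_similarity(lonely, idx$works)
  expect_equal(max(sc2), 0.4)
  e <- match_full_citation(lonely, idx, threshold = 0.8)
  expect_equal(e$method, "unmatched")

  # container alias + volume + year + authors clears the default threshold
  aliased <- parse_microcitation("Li & Wang, Front. Microbiol. 12: 33 (2021)")
  expect_equal(aliased$container, "Frontiers in Microbiology")
  sc3 <- citation_similarity(aliased, idx$works)
  expect_gte(max(sc3), 0.8)
})

test_that("raising the similarity threshold never gains matches", {
  corpus <- generate_corpus(corpus_spec(seed = 5))
  # strip pages so everything rides the full-citation path
  idx <- build_index(corpus$works |>
                       dplyr::mutate(page_start = NA_integer_, page_end = NA_integer_,
                                     article_number = NA_character_))
  mc <- parse_microcitation(corpus$names$citation_string[1:80], on_failure = "na")
  matched <- sapply(c(0.2, 0.5, 0.8, 0.95), function(th) {
    sum(match_full_citation(mc, idx, threshold = th)$method == "full_citation")
  })
  expect_true(all(diff(matched) <= 0))
})

test_that("journal/volume mismatch yields an advisory suggestion, never a match", {
  idx <- build_index(fixture_works())
  mc <- parse_microcitation(
    "Hu, Dai, Zhao, Guo, Tuo, Rao, Qi, Zhang, Li & Zhang, IMA Fungus 83: 166 (2021)")
  e <- resolve_microcitation(mc, idx)
  expect_equal(e$method, "unmatched")
  expect_true(is.na(e$work_id))
  expect_true(has_flag(e, "journal_volume_mismatch"))
  expect_true(has_flag(e, "suggested_alternative"))
  expect_equal(e$suggestion_work_id, "mk-83-161")

  # nothing matches anywhere: no suggestion
  nada <- detect_mismatch(parse_microcitation("IMA Fungus 999: 5 (1800)"), idx)
  expect_equal(nada$method, "unmatched")
  expect_true(is.na(nada$suggestion_work_id))
  expect_equal(nada$flags, "")

  # two alternative containers qualify: ambiguous, no suggestion
  works2 <- dplyr::bind_rows(
    fixture_works(),
    works_tbl("zk-83-150", "ZooKeys", volume = "83", page_start = 150L,
              page_end = 175L, year = 2021L,
              identifiers = pid_set(doi = "10.3897/zookeys.83.1"))
  )
  two_alt <- detect_mismatch(mc, build_index(works2))
  expect_true(is.na(two_alt$suggestion_work_id))
  expect_true(has_flag(two_alt, "ambiguous"))
  expect_equal(two_alt$method, "unmatched")
})

test_that("resolution agrees with the brute-force oracle on synthetic corpora", {
  for (s in c(101, 202)) {
    corpus <- generate_corpus(corpus_spec(seed = s))
    got <- resolve_names(corpus$names, build_index(corpus$works))
    want <- oracle_resolve_corpus(corpus$names, corpus$works)
    expect_identical(got$work_id, want$work_id)
    expect_identical(got$method, want$method)
  }
})

test_that("uncorrupted corpora resolve with perfect precision and recall", {
  corpus <- generate_corpus(corpus_spec(seed = 303))
  got <- resolve_names(corpus$names, build_index(corpus$works))
  truth <- corpus$truth$work_id[match(got$lsid, corpus$truth$lsid)]
  expect_true(all(!is.na(got$work_id)))
  expect_identical(got$work_id, truth)
})
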