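test_that("LSID parsing handles nomenclator identifiers and round-trips", {
  p <- parse_lsid("urn:lsid:indexfungorum.org:names:839249")
  expect_equal(p$authority, "indexfungorum.org")
  expect_equal(p$namespace, "names")
  expect_equal(p$object_id, "839249")
  expect_true(is.na(p$revision))

  p2 <- parse_lsid("urn:lsid:indexfungorum.org:names:840943")
  expect_equal(p2$object_id, "840943")

  # authority case folds; everything else round-trips byte-identically
  expect_equal(format_lsid(parse_lsid("urn:lsid:IndexFungorum.ORG:names:1")),
               "urn:lsid:indexfungorum.org:names:1")
  withr::with_seed(11, {
    for (i in 1:25) {
      x <- sprintf("urn:lsid:%s.org:%s:%d%s",
                   paste(sample(letters, 6), collapse = ""),
                   sample(c("names", "taxa"), 1), sample.int(1e6, 1),
                   sample(c("", ":2"), 1))
      expect_identical(format_lsid(parse_lsid(x)), x)
    }
  })

  expect_error(parse_lsid("https://doi.org/10.1234/x"),
               class = "taxolink_malformed_identifier")
  expect_error(parse_lsid("urn:lsid:only:two"),
               class = "taxolink_malformed_identifier")
  expect_error(parse_lsid(""), class = "taxolink_malformed_identifier")
})

test_that("DOI normalization strips resolvers, folds case and is idempotent", {
  expect_equal(normalize_doi("https://doi.org/10.3897/mycokeys.83.72325"),
               "10.3897/mycokeys.83.72325")
  expect_equal(normalize_doi("10.3389/fmicb.2021.737541"),
               "10.3389/fmicb.2021.737541")
  expect_equal(normalize_doi("doi:10.1234/ABC"), "10.1234/abc")
  expect_equal(normalize_doi("http://dx.doi.org/10.1234/x"), "10.1234/x")
  for (x in c("10.1/a", "https://doi.org/10.5281/zenodo.7211134", "DOI:10.2/B.c")) {
    expect_identical(normalize_doi(normalize_doi(x)), normalize_doi(x))
  }
  expect_error(normalize_doi("banana"), class = "taxolink_malformed_identifier")
  expect_error(normalize_doi("11.1234/x"), class = "taxolink_malformed_identifier")
})

test_that("identifier classification separates the tracked kinds", {
  got <- classify_identifier(c(
    "https://doi.org/10.3897/mycokeys.83.72325",
    "https://hdl.handle.net/10199/12345",
    "https://www.jstor.org/stable/4110316",
    "https://biostor.org/reference/100",
    "https://www.biodiversitylibrary.org/page/29372205",
    "https://example.org/paper.PDF",
    "https://example.org/paper",
    "Q105740570",
    "https://www.wikidata.org/wiki/Q105740570"
  ))
  expect_equal(got$kind, c("DOI", "Handle", "JSTOR", "BioStor", "BHL",
                           "PDF", "URL", "WikidataQID", "WikidataQID"))
  expect_equal(got$value[1], "10.3897/mycokeys.83.72325")
  expect_equal(got$value[8], "Q105740570")
  expect_equal(got$value[9], "Q105740570")
  expect_error(classify_identifier("not an identifier"),
               class = "taxolink_malformed_identifier")
})

test_that("LSID equivalence follows the shared-local-id rule", {
  a <- "urn:lsid:indexfungorum.org:names:550000"
  expect_true(lsids_equivalent(a, a))
  expect_true(lsids_equivalent(a, "urn:lsid:mycobank.org:names:550000"))
  expect_false(lsids_equivalent(a, "urn:lsid:mycobank.org:names:550001"))
  expect_false(lsids_equivalent(a, "urn:lsid:ipni.org:names:550000"))
  # rules are data: an empty rule set keeps only identity
  none <- tibble::tibble(authority_a = character(), authority_b = character())
  expect_false(lsids_equivalent(a, "urn:lsid:mycobank.org:names:550000", rules = none))
})

test_that("preferred identifier follows precedence, invariant under permutation", {
  ids <- pid_set(url = "https://example.org/x", doi = "10.1234/x")
  expect_equal(preferred_identifier(ids)$kind, "DOI")
  expect_equal(preferred_identifier(pid_set(url = "https://example.org/x"))$kind, "URL")
  expect_error(preferred_identifier(pid_set()), class = "taxolink_empty_set")

  big <- pid_set(pdf = "https://a.org/x.pdf", url = "https://a.org/x",
                 bhl = "123", doi = "10.1/b", doi = "10.1/a")
  withr::with_seed(3, {
    for (i in 1:10) {
      perm <- big[sample.int(nrow(big)), ]
      expect_equal(preferred_identifier(perm)$value, "10.1/a")
    }
  })
})

test_that("fragment identifiers serialize page positions and round-trip", {
  f <- fragment_identifier("https://doi.org/10.1234/x", 7)
  expect_equal(f, "https://doi.org/10.1234/x#page=7")
  back <- parse_fragment_identifier(f)
  expect_equal(back$base, "https://doi.org/10.1234/x")
  expect_equal(back$page_index, 7L)
  expect_error(fragment_identifier("x", 0), class = "taxolink_malformed_identifier")
})
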