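test_that("a DOI-bearing name yields exactly the three modelled triples", {
  names <- name_records("urn:lsid:indexfungorum.org:names:839249",
                        "Cordyceps changchunensis",
                        "Hu, MycoKeys 83: 166 (2021)")
  work <- works_tbl("w1", "MycoKeys", volume = "83", year = 2021L,
                    identifiers = pid_set(doi = "10.3897/mycokeys.83.72325"))
  tr <- name_to_triples(names, work)
  expect_equal(nrow(tr), 3)
  v <- kg_vocabulary()
  expect_true(all(tr$subject == "urn:lsid:indexfungorum.org:names:839249"))
  link <- tr[tr$predicate == v[["isBasedOn"]], ]
  expect_equal(link$object, "https://doi.org/10.3897/mycokeys.83.72325")
  expect_true(link$object_iri)
  lab <- tr[tr$predicate == v[["name"]], ]
  expect_equal(lab$object, "Cordyceps changchunensis")
  expect_false(lab$object_iri)

  nodoi <- works_tbl("w2", "Mycotaxon", year = 1992L,
                     identifiers = pid_set(url = "https://example.org/x"))
  expect_error(name_to_triples(names, nodoi), class = "taxolink_no_doi")
})

test_that("batches emit three triples per DOI-bearing name", {
  corpus <- generate_corpus(corpus_spec(seed = 23))
  doi <- purrr::map_chr(corpus$works$identifiers, function(ids) {
    v <- ids$value[ids$kind == "DOI"]; if (length(v)) v[1] else NA_character_
  })
  wk <- corpus$works[match(corpus$truth$work_id, corpus$works$work_id), ]
  keep <- !is.na(doi[match(corpus$truth$work_id, corpus$works$work_id)])
  tr <- name_to_triples(corpus$names[keep, ], wk[keep, ])
  expect_equal(nrow(tr), 3 * sum(keep))
})

test_that("person-record cleaning repairs what it can and rejects what it cannot", {
  p <- clean_person_record(list(
    orcid = " https://orcid.org/0000-0002-7101-9767\n",
    given = " Janet ", family = "Botan",
    works = c("doi.org/10.1/abc ", "not a doi"),
    affiliations = list(list(org_name = "U", scheme = "RINGGOLD", value = " 41803 "))
  ))
  expect_equal(p$orcid, "https://orcid.org/0000-0002-7101-9767")
  expect_equal(p$works, "10.1/abc")   # invalid DOI field dropped, valid one kept
  expect_equal(p$affiliations[[1]]$value, "41803")

  # scheme repair
  p2 <- clean_person_record(list(orcid = "orcid.org/0000-0002-7101-9767"))
  expect_equal(p2$orcid, "https://orcid.org/0000-0002-7101-9767")

  err <- tryCatch(clean_person_record(list(orcid = "not-an-id")), condition = identity)
  expect_s3_class(err, "taxolink_rejection")
  expect_equal(err$reason, "bad-orcid")
  err2 <- tryCatch(clean_person_record(list()), condition = identity)
  expect_equal(err2$reason, "empty-record")
})

test_that("person triples follow the counted shape and share organisation nodes", {
  p <- clean_person_record(list(
    orcid = "https://orcid.org/0000-0002-0001-0001", given = "A", family = "B",
    affiliations = list(list(org_name = "RBGE", scheme = "RINGGOLD", value = "41803")),
    works = c("10.1/a", "10.1/b")
  ))
  tr <- person_to_triples(p)
  expect_equal(nrow(tr), 5)  # type + name + 1 affiliation + 2 authorship
  v <- kg_vocabulary()
  expect_equal(sum(tr$predicate == v[["creator"]]), 2)
  expect_equal(tr$object[tr$predicate == v[["affiliation"]]], "urn:org:RINGGOLD:41803")

  q <- clean_person_record(list(
    orcid = "https://orcid.org/0000-0002-0001-0002", given = "C", family = "D",
    affiliations = list(list(org_name = "RBGE", scheme = "RINGGOLD", value = "41803"))
  ))
  tq <- person_to_triples(q)
  expect_equal(nrow(tq), 3)  # no works: type + name + affiliation
  expect_equal(tq$object[tq$predicate == v[["affiliation"]]],
               tr$object[tr$predicate == v[["affiliation"]]])
})

test_that("N-Triples writing round-trips with identical triple count", {
  tr <- triples(
    subject = c("urn:lsid:example.org:names:1", "urn:lsid:example.org:names:1"),
    predicate = c(kg_vocabulary()[["name"]], kg_vocabulary()[["isBasedOn"]]),
    object = c("Aus bus \"quoted\" \t tabbed", "https://doi.org/10.1/a"),
    object_iri = c(FALSE, TRUE)
  )
  f <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(tr, f)
  back <- read_ntriples(f)
  expect_equal(nrow(back), nrow(tr))
  expect_identical(back$object[1], "Aus bus \"quoted\" \t tabbed")
  expect_identical(back$subject, tr$subject)
})

test_that("graph assembly uses set semantics and reports malformed lines", {
  v <- kg_vocabulary()
  t1 <- triples(paste0("urn:x:", 1:3), rep(v[["name"]], 3), letters[1:3], rep(FALSE, 3))
  t2 <- dplyr::bind_rows(t1[1, ], triples(paste0("urn:y:", 1:3), rep(v[["name"]], 3),
                                          letters[4:6], rep(FALSE, 3)))
  f1 <- withr::local_tempfile(fileext = ".nt")
  f2 <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(t1, f1); write_ntriples(t2, f2)
  g <- assemble_graph(c(f1, f2))
  expect_equal(nrow(g), 6)  # 3 + 4 with 1 duplicate

  fe <- withr::local_tempfile(fileext = ".nt")
  writeLines(character(), fe)
  expect_equal(nrow(assemble_graph(fe)), 0)

  fb <- withr::local_tempfile(fileext = ".nt")
  writeLines(c("<urn:a> <urn:p> <urn:b> .", "this is not a triple"), fb)
  err <- tryCatch(assemble_graph(fb), condition = identity)
  expect_s3_class(err, "taxolink_ntriples_parse")
  expect_match(conditionMessage(err), "line 2")
})

make_affiliation_graph <- function() {
  names <- name_records(
    c("urn:lsid:ipni.org:names:1", "urn:lsid:indexfungorum.org:names:2"),
    c("Planta prima", "Fungus primus"),
    c("x", "y"))
  works <- works_tbl(c("w1", "w2"), c("J", "K"), year = c(2000L, 2001L),
                     identifiers = list(pid_set(doi = "10.1/plant"),
                                        pid_set(doi = "10.1/fungus")))
  p1 <- clean_person_record(list(
    orcid = "https://orcid.org/0000-0002-0001-0001", given = "Ann", family = "Auth",
    affiliations = list(list(org_name = "RBGE", scheme = "RINGGOLD", value = "41803")),
    works = "10.1/plant"))
  p2 <- clean_person_record(list(
    orcid = "https://orcid.org/0000-0002-0001-0002", given = "Bob", family = "Other",
    affiliations = list(list(org_name = "Elsewhere", scheme = "RINGGOLD", value = "99999")),
    works = "10.1/fungus"))
  dplyr::bind_rows(
    name_to_triples(names, works),
    person_to_triples(p1),
    person_to_triples(p2)
  )
}

test_that("the affiliation query returns the hand-traced join", {
  g <- make_affiliation_graph()
  got <- query_org_authors(g, "RINGGOLD", "41803")
  expect_equal(got$person, "https://orcid.org/0000-0002-0001-0001")
  expect_equal(got$name, "Ann Auth")

  expect_equal(nrow(query_org_authors(g, "RINGGOLD", "00000")), 0)

  # authority filter: RBGE person authored the ipni.org name's work only
  expect_equal(nrow(query_org_authors(g, "RINGGOLD", "41803",
                                      lsid_authority = "ipni.org")), 1)
  expect_equal(nrow(query_org_authors(g, "RINGGOLD", "41803",
                                      lsid_authority = "indexfungorum.org")), 0)
})

test_that("the affiliation query matches a brute-force nested-loop join", {
  g <- make_affiliation_graph()
  v <- kg_vocabulary()
  expected <- character()
  for (i in seq_len(nrow(g))) {
    if (g$predicate[i] != v[["isBasedOn"]]) next
    for (j in seq_len(nrow(g))) {
      if (g$predicate[j] != v[["creator"]] || g$subject[j] != g$object[i]) next
      for (k in seq_len(nrow(g))) {
        if (g$predicate[k] == v[["affiliation"]] &&
            g$subject[k] == g$object[j] &&
            g$object[k] == "urn:org:RINGGOLD:41803") {
          expected <- c(expected, g$object[j])
        }
      }
    }
  }
  got <- query_org_authors(g, "RINGGOLD", "41803")
  expect_setequal(got$person, unique(expected))
})
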