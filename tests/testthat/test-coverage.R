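test_that("identifier counting follows the once-per-kind-plus-Any definition", {
  names <- name_records(
    paste0("urn:lsid:example.org:names:", 1:3),
    c("Aa bb", "Cc dd", "Ee ff"),
    c("cite 1", "cite 2", ""),
    source_db = c("IndexFungorum", "IndexFungorum", "IPNI"))
  entries <- tibble::tibble(
    lsid = names$lsid,
    identifiers = list(pid_set(doi = "10.1/a", url = "https://x.org/a"),
                       pid_set(), pid_set(qid = "Q1")))
  counts <- summarize_by_identifier(entries, names)
  pick <- function(src, st) counts$count[counts$source == src & counts$statistic == st]
  expect_equal(pick("IndexFungorum", "DOI"), 1)
  expect_equal(pick("IndexFungorum", "URL"), 1)
  expect_equal(pick("IndexFungorum", "Any"), 1)  # one name, counted once
  expect_equal(pick("IndexFungorum", "TotalNames"), 2)
  expect_equal(pick("IndexFungorum", "NamesWithPublications"), 2)
  expect_equal(pick("IPNI", "NamesWithPublications"), 0)  # empty citation string
  expect_equal(pick("Total", "Any"), 2)
  expect_equal(pick("Total", "TotalNames"), 3)

  empty <- summarize_by_identifier(entries[0, ], names[0, ])
  expect_true(all(empty$count == 0))
})

test_that("totals are row sums across sources for every statistic", {
  counts <- counts_add_totals(reported_source_counts())
  per_source <- counts[counts$source != "Total", ]
  tot <- counts[counts$source == "Total", ]
  for (st in unique(tot$statistic)) {
    expect_equal(tot$count[tot$statistic == st],
                 sum(per_source$count[per_source$statistic == st]))
  }
})

test_that("coverage percentage is Any over NamesWithPublications", {
  counts <- tibble::tibble(
    source = "X", statistic = c("NamesWithPublications", "Any"), count = c(200L, 50L))
  expect_equal(coverage_percentage(counts_add_totals(counts)), 25)
  all_mapped <- tibble::tibble(
    source = "X", statistic = c("NamesWithPublications", "Any"), count = c(10L, 10L))
  expect_equal(coverage_percentage(counts_add_totals(all_mapped)), 100)
  zero <- tibble::tibble(
    source = "X", statistic = c("NamesWithPublications", "Any"), count = c(0L, 0L))
  expect_error(coverage_percentage(counts_add_totals(zero)),
               class = "taxolink_division_by_zero")
})

decade_fixture <- function() {
  tibble::tibble(
    lsid = paste0("urn:lsid:example.org:names:", 1:14),
    container = c(rep("Old Series", 5), rep("New Journal", 9)),
    year = c(1901, 1902, 1911, 1912, 1913, rep(2001, 2), rep(2011, 6), 1700),
    name_string = "x"
  )
}

test_that("decade matrix bins, orders by modal decade and reports PID share", {
  nm <- decade_fixture()
  entries <- tibble::tibble(
    lsid = nm$lsid,
    identifiers = c(rep(list(pid_set(doi = "10.1/x")), 4),
                    rep(list(pid_set()), 10)))
  m <- decade_container_matrix(nm, entries, top_k = 50)
  df <- tibble::as_tibble(m)
  # Old Series: 1900s->2, 1910s->3 => modal decade 1910
  ord <- attr(m, "container_order")
  expect_equal(ord$modal_decade[ord$container == "Old Series"], 1910)
  expect_equal(ord$modal_decade[ord$container == "New Journal"], 2010)
  # earlier modal decade first
  expect_equal(ord$container, c("Old Series", "New Journal"))
  # out-of-window 1700 name goes to "other", not dropped
  expect_equal(df$n[df$container == "New Journal" & df$decade == "other"], 1)
  # cell sums equal the dated names of the selected containers
  expect_equal(sum(df$n), 14)
  # Old Series: 4 of 5 names mapped -> 80%
  pid <- attr(m, "pid_percentage")
  expect_equal(pid$pid_percentage[pid$container == "Old Series"], 80)
  expect_s3_class(ggplot2::autoplot(m), "gg")
})

test_that("the long-tail curve accumulates against the whole corpus", {
  nm <- tibble::tibble(container = rep(c("A", "B", "C", "D"), c(50, 30, 20, 100)))
  lt <- long_tail_curve(nm, top_n = 3)
  expect_equal(lt$container, c("D", "A", "B"))
  expect_equal(lt$cumulative_pct, c(50, 75, 90))
  # worked arithmetic: top counts 50/30/20 in a 200-name corpus -> 25/40/50%
  lt2 <- long_tail_curve(tibble::tibble(
    container = c(rep(c("A", "B", "C"), c(50, 30, 20)), paste0("r", 1:100))),
    top_n = 3)
  expect_equal(lt2$container, c("A", "B", "C"))
  expect_equal(lt2$cumulative_pct, c(25, 40, 50))
  lt2 <- long_tail_curve(tibble::tibble(
    container = c(rep(c("A", "B", "C"), c(50, 30, 20)), paste0("r", 1:100))),
    top_n = 200)
  # monotone, bounded
  expect_true(all(diff(lt2$cumulative_pct) >= 0))
  expect_lte(max(lt2$cumulative_pct), 100)

  one <- long_tail_curve(tibble::tibble(container = rep("only", 7)), top_n = 5)
  expect_equal(one$cumulative_pct, 100)
  expect_equal(nrow(one), 1)  # curve length capped by container count
  expect_s3_class(ggplot2::autoplot(one), "gg")
})
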