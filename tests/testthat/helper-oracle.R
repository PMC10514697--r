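# Independent brute-force resolution oracle: a plain O(N) scan over all
# works for every query, written with base-R loops and no reuse of the
# package's index or cascade. Mirrors the documented decision rules:
# page containment under (canonical container, volume) with year +/- 1 and
# narrowest-range/exact-start/lowest-id tie-break, then article-number
# equality under the same container.

oracle_resolve_one <- function(q, works_flat) {
  w <- works_flat
  if (!is.na(q$page) && !is.na(q$container) && !is.na(q$volume) &&
      !isTRUE(q$continuous_key)) {
    hit <- which(
      w$container_canon == q$container & !is.na(w$volume) & w$volume == q$volume &
        !is.na(w$page_start) & !is.na(w$page_end) &
        w$page_start <= q$page & q$page <= w$page_end &
        (is.na(q$year) | is.na(w$year) | abs(w$year - q$year) <= 1)
    )
    if (length(hit) > 0) {
      width <- w$page_end[hit] - w$page_start[hit]
      exact <- w$page_start[hit] == q$page
      ord <- order(width, !exact, w$work_id[hit])
      return(list(work_id = w$work_id[hit[ord[1]]], method = "page_range"))
    }
  }
  if (!is.na(q$article_number) && !is.na(q$container)) {
    hit <- which(
      w$container_canon == q$container &
        ((!is.na(w$article_number) & w$article_number == q$article_number) |
           (!is.na(w$doi_tail) & w$doi_tail == q$article_number))
    )
    if (length(hit) > 0) {
      ord <- order(w$work_id[hit])
      return(list(work_id = w$work_id[hit[ord[1]]], method = "article_number"))
    }
  }
  list(work_id = NA_character_, method = "unmatched")
}

# Flatten a works tibble for the oracle; canonicalization is recomputed
# here from first principles (lower-case, squashed) rather than through
# the package's alias machinery, so corpora must use container names that
# are stable under normalize_container (the synthetic generator's are).
oracle_flatten_works <- function(works) {
  doi <- vapply(works$identifiers, function(ids) {
    v <- ids$value[ids$kind == "DOI"]
    if (length(v)) v[1] else NA_character_
  }, character(1))
  data.frame(
    work_id = works$work_id,
    container_canon = taxolink::normalize_container(works$container),
    volume = works$volume,
    page_start = works$page_start, page_end = works$page_end,
    year = works$year,
    article_number = works$article_number,
    doi_tail = ifelse(is.na(doi), NA_character_, sub("^.*[./]", "", doi)),
    stringsAsFactors = FALSE
  )
}

# (container, volume) keys where >= k works share page_start == 1: the
# oracle, like the engine, refuses page matching there
oracle_continuous_keys <- function(wf, k = 5) {
  key <- paste(wf$container_canon, wf$volume, sep = "\r")
  tab <- table(key[!is.na(wf$page_start) & wf$page_start == 1])
  names(tab)[tab >= k]
}

oracle_resolve_corpus <- function(names, works) {
  wf <- oracle_flatten_works(works)
  cont <- oracle_continuous_keys(wf)
  mc <- taxolink::parse_microcitation(names$citation_string, on_failure = "na")
  out_id <- character(nrow(mc))
  out_method <- character(nrow(mc))
  for (i in seq_len(nrow(mc))) {
    q <- as.list(mc[i, ])
    q$continuous_key <- paste(q$container, q$volume, sep = "\r") %in% cont
    r <- oracle_resolve_one(q, wf)
    out_id[i] <- r$work_id
    out_method[i] <- r$method
  }
  data.frame(lsid = names$lsid, work_id = out_id, method = out_method,
             stringsAsFactors = FALSE)
}

# small fixture bibliography used across match-engine tests
fixture_works <- function() {
  works_tbl(
    work_id = c("mk-83-161", "fm-12-737541", "mt-45-113", "mt-45-101"),
    container = c("MycoKeys", "Frontiers in Microbiology", "Mycotaxon", "Mycotaxon"),
    volume = c("83", "12", "45", "45"),
    page_start = c(161L, NA, 113L, 101L),
    page_end = c(180L, NA, 129L, 125L),
    year = c(2021L, 2021L, 1992L, 1992L),
    title = c("Hidden diversity of wood-inhabiting fungi",
              "Endophytic fungi of a mangrove host",
              "New records of corticioid fungi", "Corticioid fungi revisited"),
    authors = list(c("Hu", "Dai", "Zhao", "Zhang"), c("Li", "Wang"),
                   "Ginns", "Ginns"),
    identifiers = list(pid_set(doi = "10.3897/mycokeys.83.72325", qid = "Q105740570"),
                       pid_set(doi = "10.3389/fmicb.2021.737541"),
                       pid_set(url = "https://example.org/mycotaxon/45/113"),
                       pid_set(doi = "10.9999/mt.45.101")),
    article_number = c(NA, "737541", NA, NA)
  )
}
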