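# Synthetic corpus generator: name databases, bibliographies and person
# records with known ground-truth links, plus a corruption model emulating
# the error archetypes seen in real nomenclator records (wrong journal,
# perturbed volume, page outside the article, year drift).

#' Specify a synthetic corpus
#'
#' Defaults describe a small but structurally realistic corpus: 10 journals
#' with 5 volumes of 5 articles each and 2 names per article (500 names,
#' 250 works). Volume numbers are globally unique across journals
#' (journal *i* holds volumes `(i-1)*V+1 .. i*V`), mirroring the situation
#' where a cited volume simply does not exist in the wrong journal — the
#' signal that makes journal/volume mismatches detectable. A configurable
#' fraction of journals uses continuous article numbering (every article
#' starts on page 1 and is cited by article number).
#'
#' @param n_journals,volumes_per_journal,articles_per_volume,names_per_article
#'   Positive integers.
#' @param continuous_numbering_fraction Fraction of journals using
#'   continuous article numbering, default 0.1.
#' @param doi_fraction Fraction of works carrying a DOI, default 0.9
#'   (continuous-numbering works always carry one: their article number is
#'   the DOI tail).
#' @param qid_fraction Fraction of works carrying a Wikidata QID, default
#'   0.3.
#' @param corruption_rates Named list/vector with rates in `[0, 1]` for
#'   `wrong_journal`, `wrong_volume`, `page_offset`, `year_offset`; all 0 by
#'   default.
#' @param seed Integer seed; fully determines the corpus.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_journals = 10, volumes_per_journal = 5,
                        articles_per_volume = 5, names_per_article = 2,
                        continuous_numbering_fraction = 0.1,
                        doi_fraction = 0.9, qid_fraction = 0.3,
                        corruption_rates = list(wrong_journal = 0, wrong_volume = 0,
                                                page_offset = 0, year_offset = 0),
                        seed = 1L) {
  spec <- list(
    n_journals = as.integer(n_journals),
    volumes_per_journal = as.integer(volumes_per_journal),
    articles_per_volume = as.integer(articles_per_volume),
    names_per_article = as.integer(names_per_article),
    continuous_numbering_fraction = continuous_numbering_fraction,
    doi_fraction = doi_fraction, qid_fraction = qid_fraction,
    corruption_rates = as.list(corruption_rates), seed = as.integer(seed)
  )
  sizes <- unlist(spec[1:4])
  if (any(is.na(sizes) | sizes < 1)) {
    abort("Corpus dimensions must be positive integers", class = "taxolink_invalid_spec")
  }
  fr <- c(spec$continuous_numbering_fraction, spec$doi_fraction, spec$qid_fraction,
          unlist(spec$corruption_rates))
  if (any(fr < 0 | fr > 1)) {
    abort("Fractions and corruption rates must lie in [0, 1]",
          class = "taxolink_invalid_spec")
  }
  structure(spec, class = "corpus_spec")
}

SYLLABLES <- c("ba", "co", "di", "fu", "ga", "ho", "ki", "lu", "my", "ne",
               "or", "pa", "qu", "ri", "sa", "to", "ul", "ve", "xa", "zo")

rand_word <- function(n, n_syll = 3, capitalize = TRUE) {
  w <- vapply(seq_len(n), function(i) {
    paste(sample(SYLLABLES, n_syll, replace = TRUE), collapse = "")
  }, character(1))
  if (capitalize) paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w))) else w
}

#' Generate a synthetic corpus with ground truth
#'
#' Builds journals, works, taxonomic names with microcitation strings
#' rendered from their true works, ORCID-style person records, and the
#' ground-truth LSID-to-work mapping. Within each sequentially paginated
#' volume, articles occupy contiguous non-overlapping page ranges;
#' continuous-numbering journals start every article on page 1 and cite by
#' article number (which doubles as the DOI tail). Synthetic LSIDs use the
#' authority `example.org` so they are unmistakably artificial. The seed in
#' the spec fully determines the output.
#'
#' @param spec A [corpus_spec()].
#' @return List with tibbles `names`, `works`, `persons` (list of person
#'   records), `truth` (`lsid`, `work_id`) and the `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  J <- spec$n_journals; V <- spec$volumes_per_journal
  A <- spec$articles_per_volume; Np <- spec$names_per_article
  n_cont <- round(spec$continuous_numbering_fraction * J)
  suffix <- paste0(LETTERS[((seq_len(J) - 1) %/% 26) %% 26 + 1],
                   LETTERS[(seq_len(J) - 1) %% 26 + 1])
  journals <- tibble(
    journal_idx = seq_len(J),
    container = paste("Acta", rand_word(J, 3), suffix),
    continuous = seq_len(J) <= n_cont,
    start_year = sample(1850:2000, J, replace = TRUE)
  )

  works <- tidyr::expand_grid(journal_idx = seq_len(J), vol_idx = seq_len(V),
                              art_idx = seq_len(A)) |>
    left_join(journals, by = "journal_idx") |>
    mutate(
      volume = as.character((.data$journal_idx - 1) * V + .data$vol_idx),
      year = .data$start_year + (.data$vol_idx - 1L),
      work_id = sprintf("w%04d", dplyr::row_number()),
      n_pages = sample(4:30, dplyr::n(), replace = TRUE)
    ) |>
    group_by(.data$journal_idx, .data$vol_idx) |>
    mutate(
      page_start = dplyr::if_else(.data$continuous, 1L,
                                  as.integer(1 + dplyr::lag(cumsum(.data$n_pages), default = 0))),
      page_end = as.integer(.data$page_start + .data$n_pages - 1L)
    ) |>
    ungroup() |>
    mutate(
      article_number = dplyr::if_else(
        .data$continuous, sprintf("%06d", 700000 + dplyr::row_number()), NA_character_),
      slug = tolower(gsub("[^A-Za-z]", "", .data$container)),
      doi = dplyr::case_when(
        .data$continuous ~ sprintf("10.9999/%s.%d.%s", substr(.data$slug, 1, 8),
                                   .data$year, .data$article_number),
        stats::runif(dplyr::n()) < spec$doi_fraction ~
          sprintf("10.9999/%s.%s.%d", substr(.data$slug, 1, 8), .data$volume,
                  .data$page_start),
        TRUE ~ NA_character_
      ),
      qid = dplyr::if_else(stats::runif(dplyr::n()) < spec$qid_fraction,
                           sprintf("Q%d", 90000000 + dplyr::row_number()),
                           NA_character_),
      title = paste("On", rand_word(dplyr::n(), 3), "and its allies"),
      n_auth = sample(1:3, dplyr::n(), replace = TRUE)
    )
  works$authors <- purrr::map(works$n_auth, function(k) rand_word(k, 2))
  works$identifiers <- purrr::pmap(list(works$doi, works$qid),
                                   function(d, q) pid_set(doi = d, qid = q))
  works_out <- works_tbl(
    work_id = works$work_id, container = works$container, volume = works$volume,
    page_start = works$page_start, page_end = works$page_end, year = works$year,
    title = works$title, authors = works$authors, identifiers = works$identifiers,
    article_number = works$article_number
  )

  name_rows <- works |>
    select("work_id", "container", "volume", "page_start", "page_end",
           "year", "continuous", "article_number", "authors") |>
    tidyr::uncount(Np, .id = "name_idx")
  cited_page <- with(name_rows, as.integer(
    page_start + floor(stats::runif(nrow(name_rows)) * (page_end - page_start + 1))
  ))
  author_block <- purrr::map_chr(name_rows$authors, function(a) {
    if (length(a) > 1) {
      paste0(paste(a[-length(a)], collapse = ", "), " & ", a[length(a)])
    } else a
  })
  citation <- ifelse(
    name_rows$continuous,
    sprintf("%s, volume %s, issue no. %s",
            name_rows$container, name_rows$volume, name_rows$article_number),
    sprintf("%s, %s %s: %d (%d)", author_block, name_rows$container,
            name_rows$volume, cited_page, name_rows$year)
  )
  names_out <- name_records(
    lsid = sprintf("urn:lsid:example.org:names:%d", seq_len(nrow(name_rows))),
    name_string = paste(rand_word(nrow(name_rows), 3),
                        rand_word(nrow(name_rows), 3, capitalize = FALSE)),
    citation_string = citation,
    rank = "species",
    source_db = "other"
  )
  truth <- tibble(lsid = names_out$lsid, work_id = name_rows$work_id)

  doi_pool <- works$doi[!is.na(works$doi)]
  n_persons <- max(3L, J)
  orgs <- tibble(scheme = "RINGGOLD",
                 value = as.character(40000 + seq_len(max(2L, J %/% 3))))
  persons <- purrr::map(seq_len(n_persons), function(i) {
    o <- orgs[sample.int(nrow(orgs), 1), ]
    list(
      orcid = sprintf("https://orcid.org/0000-0002-%04d-%04d", i, (7 * i) %% 10000),
      given = rand_word(1, 2), family = rand_word(1, 2),
      affiliations = list(list(org_name = paste("Institute of", rand_word(1, 3)),
                               scheme = o$scheme, value = o$value)),
      works = sample(doi_pool, min(3, length(doi_pool)))
    )
  })

  list(names = names_out, works = works_out, persons = persons,
       truth = truth, spec = spec)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Corrupt a synthetic corpus
#'
#' Applies each corruption independently per name with its rate:
#' `wrong_journal` swaps the cited container for another journal's,
#' `wrong_volume` perturbs the volume by ±1, `page_offset` moves the cited
#' page beyond its article's range, `year_offset` shifts the year by ±2.
#' The microcitation string is re-rendered after corruption. The log
#' records exactly which names were altered and how.
#'
#' @param corpus A [generate_corpus()] result.
#' @param rates Named list of rates; defaults to the spec's
#'   `corruption_rates`.
#' @param seed Integer seed for the corruption stream; defaults to
#'   `spec$seed + 1`.
#' @return List: `names` (corrupted name records) and `log` (tibble `lsid`,
#'   `corruption`, `before`, `after`).
#' @export
corrupt_corpus <- function(corpus, rates = NULL, seed = NULL) {
  spec <- corpus$spec
  rates <- rates %||% spec$corruption_rates
  rates <- utils::modifyList(list(wrong_journal = 0, wrong_volume = 0,
                                  page_offset = 0, year_offset = 0),
                             as.list(rates))
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    abort("Corruption rates must lie in [0, 1]", class = "taxolink_invalid_spec")
  }
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed %||% (spec$seed + 1L))

  names <- corpus$names
  works <- corpus$works
  wlut <- stats::setNames(seq_len(nrow(works)), works$work_id)
  truth_w <- works[wlut[corpus$truth$work_id], ]
  containers <- unique(works$container)
  log <- tibble(lsid = character(), corruption = character(),
                before = character(), after = character())

  # corruptions are applied by targeted substitution in the raw citation
  # string, using the ground-truth work's fields; untouched names keep
  # their citation string byte-identical
  n <- nrow(names)
  is_art <- !is.na(truth_w$article_number)
  cite <- names$citation_string
  do_journal <- stats::runif(n) < rates$wrong_journal
  do_volume <- stats::runif(n) < rates$wrong_volume
  do_page <- stats::runif(n) < rates$page_offset & !is_art
  do_year <- stats::runif(n) < rates$year_offset & !is_art

  if (any(do_journal)) {
    new_container <- vapply(truth_w$container[do_journal], function(cn) {
      pool <- setdiff(containers, cn)
      pool[sample.int(length(pool), 1)]
    }, character(1), USE.NAMES = FALSE)
    cite[do_journal] <- stringr::str_replace(
      cite[do_journal], stringr::fixed(truth_w$container[do_journal]), new_container)
    log <- dplyr::bind_rows(log, tibble(
      lsid = names$lsid[do_journal], corruption = "wrong_journal",
      before = truth_w$container[do_journal], after = new_container
    ))
  }
  if (any(do_volume)) {
    v <- as.integer(truth_w$volume[do_volume])
    nv <- as.character(v + sample(c(-1L, 1L), sum(do_volume), replace = TRUE))
    old_tok <- ifelse(is_art[do_volume],
                      paste0("volume ", truth_w$volume[do_volume], ","),
                      paste0(" ", truth_w$volume[do_volume], ":"))
    new_tok <- ifelse(is_art[do_volume],
                      paste0("volume ", nv, ","), paste0(" ", nv, ":"))
    cite[do_volume] <- stringr::str_replace(cite[do_volume],
                                            stringr::fixed(old_tok), new_tok)
    log <- dplyr::bind_rows(log, tibble(
      lsid = names$lsid[do_volume], corruption = "wrong_volume",
      before = truth_w$volume[do_volume], after = nv
    ))
  }
  if (any(do_page)) {
    old_page <- stringr::str_match(cite[do_page], ": ([0-9]+) \\(")[, 2]
    new_page <- truth_w$page_end[do_page] + sample(50:500, sum(do_page), replace = TRUE)
    cite[do_page] <- stringr::str_replace(
      cite[do_page], stringr::fixed(paste0(": ", old_page, " (")),
      paste0(": ", new_page, " ("))
    log <- dplyr::bind_rows(log, tibble(
      lsid = names$lsid[do_page], corruption = "page_offset",
      before = old_page, after = as.character(new_page)
    ))
  }
  if (any(do_year)) {
    ny <- truth_w$year[do_year] + sample(c(-2L, 2L), sum(do_year), replace = TRUE)
    cite[do_year] <- stringr::str_replace(
      cite[do_year], stringr::fixed(paste0("(", truth_w$year[do_year], ")")),
      paste0("(", ny, ")"))
    log <- dplyr::bind_rows(log, tibble(
      lsid = names$lsid[do_year], corruption = "year_offset",
      before = as.character(truth_w$year[do_year]), after = as.character(ny)
    ))
  }
  names$citation_string <- cite
  list(names = names, log = log)
}
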