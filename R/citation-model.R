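# Citation model: works, name records and the microcitation grammar.
#
# Nomenclators store literature pointers as "microcitations" -- page-level
# citations such as "IMA Fungus 83: 166 (2021)" -- rather than full
# bibliographic records. This file parses those strings into structured
# fields and renders full citation strings from work metadata.

#' Default container alias table
#'
#' Journal names arrive in abbreviated and full forms; aliases map the
#' abbreviations onto canonical container names. Shipped entries cover the
#' worked examples; users extend the table with their own corpus aliases
#' (two columns: `alias`, `canonical`).
#'
#' @return Tibble with columns `alias`, `canonical`.
#' @export
default_aliases <- function() {
  tibble::tribble(
    ~alias,              ~canonical,
    "Front. Microbiol.", "Frontiers in Microbiology",
    "IMA Fungus",        "IMA Fungus",
    "MycoKeys",          "MycoKeys",
    "Mycotaxon",         "Mycotaxon"
  )
}

fold_key <- function(x) {
  x <- tolower(stringr::str_squish(x))
  stringr::str_squish(stringr::str_replace_all(x, "[^a-z0-9 ]", " "))
}

#' Normalize a container (journal/monograph) name
#'
#' Trims and squashes whitespace, compares punctuation- and
#' case-insensitively against the alias table and its canonical names, and
#' maps known abbreviations to the canonical container name. Unknown names
#' are returned in title case. Idempotent.
#'
#' @param name Character vector of container names.
#' @param aliases Alias tibble (`alias`, `canonical`); [default_aliases()] by
#'   default.
#' @return Character vector of canonical container names.
#' @examples
#' normalize_container("  ima fungus ")
#' @export
normalize_container <- function(name, aliases = default_aliases()) {
  stopifnot(is.character(name))
  key <- fold_key(name)
  lut <- c(
    stats::setNames(aliases$canonical, fold_key(aliases$alias)),
    stats::setNames(aliases$canonical, fold_key(aliases$canonical))
  )
  hit <- lut[key]
  out <- unname(hit)
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- vapply(
      tolower(stringr::str_squish(name[miss])),
      function(s) tools::toTitleCase(s),
      character(1)
    )
  }
  out
}

# Grammar: ordered alternation, first match wins.
#   1. [authors,] <container> <volume> [(<issue>)]: <page> (<year>)
#   2. <container>, volume <v>, issue no. <n>
#   3. [authors,] <container> <volume> (<issue>): <page>      (no year)
# Page tokens that are not plain arabic numerals (roman numerals, plates)
# leave `page` unset; the token is kept in the raw string.
MC_PATTERNS <- list(
  std = paste0(
    "^(?:(.+?),\\s+)?",                       # authors block (optional)
    "([\\p{L}][\\p{L}.'\\- ]*?)\\s+",         # container: no commas/digits
    "([0-9]+[A-Za-z]?)\\s*",                  # volume
    "(?:\\(([^)]+)\\)\\s*)?",                 # issue (optional)
    ":\\s*([^()]+?)\\s*",                     # page token
    "\\(([0-9]{4})\\)\\s*$"                   # year
  ),
  artno = paste0(
    "^([^,]+),\\s*volume\\s+(\\S+?),\\s*issue\\s+no\\.?\\s*(\\S+?)\\s*",
    "(?:\\(([0-9]{4})\\))?\\s*$"
  ),
  noyear = paste0(
    "^(?:(.+?),\\s+)?",
    "([\\p{L}][\\p{L}.'\\- ]*?)\\s+",
    "([0-9]+[A-Za-z]?)\\s*",
    "\\(([^)]+)\\)\\s*",
    ":\\s*([^()]+?)\\s*$"
  )
)

mc_empty <- function(n = 1) {
  tibble(
    raw = character(n), authors = NA_character_, container = NA_character_,
    volume = NA_character_, issue = NA_character_, page = NA_integer_,
    article_number = NA_character_, year = NA_integer_
  )
}

#' Parse microcitation strings
#'
#' Parses page-level citation strings of the kinds found in nomenclator
#' records into structured fields. The grammar is an ordered alternation:
#' `"<container> <volume>[(<issue>)]: <page> (<year>)"` (any leading text
#' before the container is treated as the author block), then
#' `"<container>, volume <v>, issue no. <n>"` for continuous-article-number
#' journals, then the year-less `"<container> <volume> (<issue>): <page>"`.
#' `page` and `article_number` are mutually exclusive in one result; page
#' tokens that are not plain arabic numerals (roman numerals, plate refs)
#' leave `page` unset rather than guessing.
#'
#' @param text Character vector of raw microcitation strings.
#' @param aliases Container alias table for [normalize_container()].
#' @param on_failure `"error"` (default) raises a parse-failure condition
#'   carrying the offending raw string; `"na"` returns an all-`NA` row with
#'   `raw` preserved, convenient inside pipelines.
#' @return Tibble, one row per input: `raw`, `authors`, `container`,
#'   `volume`, `issue`, `page`, `article_number`, `year`.
#' @examples
#' parse_microcitation("Hu, Dai & Zhang, IMA Fungus 83: 166 (2021)")
#' parse_microcitation("Frontiers in Microbiology, volume 12, issue no. 737541")
#' @export
parse_microcitation <- function(text, aliases = default_aliases(),
                                on_failure = c("error", "na")) {
  stopifnot(is.character(text))
  on_failure <- match.arg(on_failure)
  n <- length(text)
  out <- mc_empty(n)
  out$raw <- text
  if (n == 0) return(out)

  todo <- rep(TRUE, n)
  blank <- is.na(text) | !nzchar(stringr::str_trim(text))

  m <- stringr::str_match(text, MC_PATTERNS$std)
  hit <- !is.na(m[, 1]) & todo & !blank
  out$authors[hit] <- m[hit, 2]
  out$container[hit] <- m[hit, 3]
  out$volume[hit] <- m[hit, 4]
  out$issue[hit] <- m[hit, 5]
  pg <- m[hit, 6]
  out$page[hit] <- ifelse(stringr::str_detect(pg, "^[0-9]+$"),
                          suppressWarnings(as.integer(pg)), NA_integer_)
  out$year[hit] <- as.integer(m[hit, 7])
  todo <- todo & !hit

  m <- stringr::str_match(text, stringr::regex(MC_PATTERNS$artno, ignore_case = TRUE))
  hit <- !is.na(m[, 1]) & todo & !blank
  out$container[hit] <- m[hit, 2]
  out$volume[hit] <- m[hit, 3]
  out$article_number[hit] <- m[hit, 4]
  out$year[hit] <- as.integer(m[hit, 5])
  todo <- todo & !hit

  m <- stringr::str_match(text, MC_PATTERNS$noyear)
  hit <- !is.na(m[, 1]) & todo & !blank
  out$authors[hit] <- m[hit, 2]
  out$container[hit] <- m[hit, 3]
  out$volume[hit] <- m[hit, 4]
  out$issue[hit] <- m[hit, 5]
  pg <- m[hit, 6]
  out$page[hit] <- ifelse(stringr::str_detect(pg, "^[0-9]+$"),
                          suppressWarnings(as.integer(pg)), NA_integer_)
  todo <- todo & !hit

  failed <- todo | blank
  if (any(failed)) {
    if (on_failure == "error") {
      abort(
        paste0("Cannot parse microcitation: ",
               paste(sprintf("\"%s\"", utils::head(text[failed], 3)), collapse = ", ")),
        class = "taxolink_parse_failure",
        raw = text[failed]
      )
    }
  }
  ok <- !failed & !is.na(out$container)
  out$container[ok] <- normalize_container(out$container[ok], aliases)
  out$authors <- stringr::str_trim(out$authors)
  out
}

#' Construct a bibliography of works
#'
#' A work is a work-level bibliographic record: the unit that is normally
#' cited and that carries persistent identifiers. `identifiers` is a
#' list-column of `tibble(kind, value)` sets (see [pid_set()]); `authors` is
#' a list-column of character vectors.
#'
#' @param work_id Character; unique opaque tokens.
#' @param container Character; publication venue.
#' @param volume,issue Character or NA.
#' @param page_start,page_end Integer or NA; `page_start <= page_end`.
#' @param year Integer or NA.
#' @param title Character or NA.
#' @param authors List of character vectors (or a single character vector for
#'   one work).
#' @param identifiers List of `tibble(kind, value)` (or one such tibble for a
#'   single work).
#' @param article_number Character or NA; explicit article-number token for
#'   continuous-publication journals.
#' @return Tibble of works.
#' @export
works_tbl <- function(work_id, container, volume = NA, issue = NA,
                      page_start = NA, page_end = NA, year = NA, title = NA,
                      authors = list(character()), identifiers = list(pid_set()),
                      article_number = NA) {
  if (is.character(authors)) authors <- list(authors)
  if (is.data.frame(identifiers)) identifiers <- list(identifiers)
  out <- tibble(
    work_id = as.character(work_id),
    container = as.character(container),
    volume = as.character(volume),
    issue = as.character(issue),
    page_start = as.integer(page_start),
    page_end = as.integer(page_end),
    year = as.integer(year),
    title = as.character(title),
    authors = authors,
    identifiers = identifiers,
    article_number = as.character(article_number)
  )
  if (anyDuplicated(out$work_id)) {
    abort("work_id must be unique", class = "taxolink_duplicate_work_id")
  }
  bad <- !is.na(out$page_start) & !is.na(out$page_end) & out$page_start > out$page_end
  if (any(bad)) abort("page_start must be <= page_end")
  out
}

#' Construct a table of taxonomic name records
#'
#' @param lsid Character; serialized LSIDs, unique within a dataset.
#' @param name_string Character; the scientific name, non-empty.
#' @param citation_string Character; raw microcitation.
#' @param rank Character or NA.
#' @param source_db One of `"IndexFungorum"`, `"IPNI"`, `"ION"`, `"other"`.
#' @return Tibble of name records.
#' @export
name_records <- function(lsid, name_string, citation_string, rank = NA,
                         source_db = "other") {
  stopifnot(all(nzchar(name_string)))
  if (anyDuplicated(lsid)) abort("lsid must be unique within a dataset")
  parse_lsid(lsid)  # validates
  tibble(
    lsid = as.character(lsid),
    name_string = as.character(name_string),
    rank = as.character(rank),
    citation_string = as.character(citation_string),
    source_db = as.character(source_db)
  )
}

#' Render a full citation string from work metadata
#'
#' One built-in author-year style:
#' `"Author1, Author2 (Year) Title. Container Volume: Start–End."` Segments
#' whose fields are absent (title, volume, pages) are dropped; container and
#' year are required. Output is deterministic: identical input yields
#' byte-identical strings.
#'
#' @param work One-row tibble (or list) with the [works_tbl()] fields.
#' @param style Style token; only `"authoryear"` is built in.
#' @return Citation string (length-1 character).
#' @export
format_citation <- function(work, style = "authoryear") {
  if (!identical(style, "authoryear")) {
    abort(paste0("Unknown citation style: ", style))
  }
  if (is.data.frame(work)) {
    stopifnot(nrow(work) == 1)
    work <- as.list(work)
    work$authors <- work$authors[[1]]
  }
  missing <- c(
    if (is.null(work$container) || is.na(work$container)) "container",
    if (is.null(work$year) || is.na(work$year)) "year"
  )
  if (length(missing)) {
    abort(paste0("Cannot format citation; missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "taxolink_missing_field", fields = missing)
  }
  authors <- work$authors %||% character()
  authors <- authors[!is.na(authors) & nzchar(authors)]
  head <- if (length(authors)) {
    paste0(paste(authors, collapse = ", "), " (", work$year, ")")
  } else {
    paste0("Anonymous (", work$year, ")")
  }
  title <- if (!is.null(work$title) && !is.na(work$title) && nzchar(work$title)) {
    paste0(" ", sub("\\.?$", ".", work$title))
  } else ""
  tail <- paste0(" ", work$container)
  if (!is.null(work$volume) && !is.na(work$volume)) {
    tail <- paste0(tail, " ", work$volume)
    if (!is.na(work$page_start %||% NA)) {
      pages <- if (!is.na(work$page_end %||% NA) && work$page_end != work$page_start) {
        paste0(work$page_start, "–", work$page_end)
      } else {
        as.character(work$page_start)
      }
      tail <- paste0(tail, ": ", pages)
    }
  }
  paste0(head, title, tail, ".")
}

#' Read name records from a TSV file
#'
#' Expected columns: `lsid`, `name`, `rank`, `citation_string`, `source`.
#'
#' @param path Path to a tab-separated file.
#' @return Tibble of name records (see [name_records()]).
#' @export
read_names_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  name_records(
    lsid = raw$lsid, name_string = raw$name, citation_string = raw$citation_string,
    rank = raw[["rank"]] %||% NA, source_db = raw[["source"]] %||% "other"
  )
}

#' Read a bibliography from CSL-like JSON or TSV
#'
#' JSON input is an array of records with fields `id`, `container-title`,
#' `volume`, `issue`, `page` (`"start-end"`), `issued` (year), `title`,
#' `author` (array of `family` names or plain strings), `DOI`, `QID`, `URL`,
#' `article-number`. TSV input uses the flat column names of [works_tbl()]
#' plus optional `doi`, `qid`, `url` columns.
#'
#' @param path Path to a `.json` or `.tsv`/`.txt` file.
#' @return Tibble of works.
#' @export
read_biblio <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- purrr::map(recs, function(r) {
      pages <- r[["page"]] %||% NA
      ps <- pe <- NA_integer_
      if (!is.na(pages[1])) {
        pp <- stringr::str_match(as.character(pages), "^([0-9]+)(?:\\s*[-–]\\s*([0-9]+))?$")
        ps <- as.integer(pp[2]); pe <- as.integer(pp[3] %||% NA)
        if (is.na(pe)) pe <- ps
      }
      auth <- purrr::map_chr(r[["author"]] %||% list(), function(a) {
        if (is.list(a)) a[["family"]] %||% a[["name"]] %||% NA_character_ else as.character(a)
      })
      ids <- pid_set(
        doi = r[["DOI"]] %||% NA, qid = r[["QID"]] %||% NA, url = r[["URL"]] %||% NA
      )
      works_tbl(
        work_id = r[["id"]], container = r[["container-title"]],
        volume = r[["volume"]] %||% NA, issue = r[["issue"]] %||% NA,
        page_start = ps, page_end = pe,
        year = as.integer(r[["issued"]] %||% NA), title = r[["title"]] %||% NA,
        authors = list(auth), identifiers = list(ids),
        article_number = r[["article-number"]] %||% NA
      )
    })
    out <- dplyr::bind_rows(rows)
    if (anyDuplicated(out$work_id)) {
      abort("work_id must be unique", class = "taxolink_duplicate_work_id")
    }
    out
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    col <- function(nm) raw[[nm]] %||% rep(NA_character_, nrow(raw))
    works_tbl(
      work_id = raw$work_id, container = raw$container,
      volume = col("volume"), issue = col("issue"),
      page_start = col("page_start"), page_end = col("page_end"),
      year = col("year"), title = col("title"),
      authors = purrr::map(col("authors"),
                           ~ if (is.na(.x)) character() else strsplit(.x, ";\\s*")[[1]]),
      identifiers = purrr::pmap(
        list(col("doi"), col("qid"), col("url")),
        function(d, q, u) pid_set(doi = d, qid = q, url = u)
      ),
      article_number = col("article_number")
    )
  }
}
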