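# Match engine: resolve parsed microcitations to works.
#
# Cascade, strongest evidence first:
#   1. page-range containment under the (canonical container, volume) key,
#   2. article-number equality against DOI tails / stored article numbers,
#   3. weighted fuzzy full-citation similarity,
# with a final diagnostic pass that looks for a unique alternative container
# (the "journal/volume mismatch" signal) when everything else fails. The
# mismatch pass only ever *suggests* a work; it never accepts one.

MATCH_METHODS <- c("page_range", "article_number", "full_citation",
                   "existing_id", "unmatched")
MATCH_FLAGS <- c("journal_volume_mismatch", "ambiguous", "year_off_by_one",
                 "suggested_alternative")

doi_tail <- function(doi) {
  # final dot- or slash-delimited token of a DOI
  stringr::str_extract(doi, "[^./]+$")
}

work_doi <- function(identifiers) {
  purrr::map_chr(identifiers, function(ids) {
    v <- ids$value[ids$kind == "DOI"]
    if (length(v)) v[1] else NA_character_
  })
}

work_qid <- function(identifiers) {
  purrr::map_chr(identifiers, function(ids) {
    v <- ids$value[ids$kind == "WikidataQID"]
    if (length(v)) v[1] else NA_character_
  })
}

#' Build a bibliography index for microcitation resolution
#'
#' Indexes works two ways: by `(canonical container, volume)` with rows
#' ordered by `page_start` (ties by `work_id`) for page-range lookup, and by
#' article-number token (the explicit article-number field plus the final
#' dot-/slash-delimited token of any DOI) for the article-number path.
#' Keys under which at least `continuous_k` works share `page_start == 1`
#' are marked continuous-numbering: page containment is meaningless there
#' ("every article starts on page 1") and the page-range path is disabled.
#'
#' @param works Tibble of works (see [works_tbl()]).
#' @param aliases Container alias table.
#' @param continuous_k Integer; threshold for flagging a
#'   continuous-numbering `(container, volume)` key. Default 5.
#' @return A `biblio_index` object.
#' @export
build_index <- function(works, aliases = default_aliases(), continuous_k = 5L) {
  if (anyDuplicated(works$work_id)) {
    abort("Duplicate work_id in bibliography", class = "taxolink_duplicate_work_id")
  }
  works <- works |>
    mutate(
      container_canon = normalize_container(.data$container, aliases),
      doi = work_doi(.data$identifiers),
      qid = work_qid(.data$identifiers)
    )
  by_cv <- works |>
    arrange(.data$container_canon, .data$volume, .data$page_start, .data$work_id)
  continuous_keys <- by_cv |>
    filter(!is.na(.data$page_start) & .data$page_start == 1L) |>
    count(.data$container_canon, .data$volume) |>
    filter(.data$n >= continuous_k) |>
    select("container_canon", "volume")
  by_artno <- dplyr::bind_rows(
    works |>
      filter(!is.na(.data$article_number)) |>
      transmute(token = .data$article_number, work_id = .data$work_id,
                container_canon = .data$container_canon),
    works |>
      filter(!is.na(.data$doi)) |>
      transmute(token = doi_tail(.data$doi), work_id = .data$work_id,
                container_canon = .data$container_canon)
  ) |> distinct()
  structure(
    list(works = works, by_cv = by_cv, by_artno = by_artno,
         continuous_keys = continuous_keys, aliases = aliases),
    class = "biblio_index"
  )
}

#' @export
print.biblio_index <- function(x, ...) {
  cat("<biblio_index> ", nrow(x$works), " works, ",
      nrow(dplyr::distinct(x$by_cv, .data$container_canon, .data$volume)),
      " (container, volume) keys, ",
      nrow(x$continuous_keys), " continuous-numbering keys\n", sep = "")
  invisible(x)
}

empty_entries <- function(n = 0) {
  tibble(
    lsid = character(n), work_id = NA_character_, method = rep("unmatched", n),
    flags = rep("", n), suggestion_work_id = NA_character_, score = NA_real_
  )
}

add_flag <- function(flags, flag, where = TRUE) {
  ifelse(where, ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag), flags)
}

#' Test whether a mapping entry carries a flag
#'
#' @param entries Mapping tibble with a `flags` column.
#' @param flag Flag name.
#' @return Logical vector.
#' @export
has_flag <- function(entries, flag) {
  stringr::str_detect(entries$flags, stringr::fixed(flag))
}

year_ok <- function(mc_year, work_year, window = 1L) {
  is.na(mc_year) | is.na(work_year) | abs(mc_year - work_year) <= window
}

# Vectorized page-range resolution over a parsed microcitation table.
# Returns one row per input mc row (keyed by .row).
resolve_page_range <- function(mc, index, year_window = 1L) {
  mc <- mc |> mutate(.row = dplyr::row_number())
  out <- empty_entries(nrow(mc))
  out$lsid <- mc[["lsid"]] %||% rep(NA_character_, nrow(mc))

  cand <- mc |>
    filter(!is.na(.data$container), !is.na(.data$volume), !is.na(.data$page)) |>
    anti_join(dplyr::rename(index$continuous_keys, container = "container_canon"),
              by = c("container", "volume")) |>
    inner_join(
      index$by_cv |>
        select(work_id2 = "work_id", container = "container_canon", "volume",
               "page_start", "page_end", work_year = "year"),
      by = c("container", "volume"),
      relationship = "many-to-many"
    ) |>
    filter(!is.na(.data$page_start), !is.na(.data$page_end),
           .data$page >= .data$page_start, .data$page <= .data$page_end,
           year_ok(.data$year, .data$work_year, year_window))

  if (nrow(cand) == 0) return(out)

  picked <- cand |>
    mutate(width = .data$page_end - .data$page_start,
           exact_start = .data$page_start == .data$page) |>
    group_by(.data$.row) |>
    mutate(n_cand = dplyr::n()) |>
    arrange(.data$width, dplyr::desc(.data$exact_start), .data$work_id2,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  out$work_id[picked$.row] <- picked$work_id2
  out$method[picked$.row] <- "page_range"
  out$flags[picked$.row] <- add_flag(out$flags[picked$.row], "ambiguous",
                                     picked$n_cand > 1)
  off <- !is.na(picked$year) & !is.na(picked$work_year) &
    picked$year != picked$work_year
  out$flags[picked$.row] <- add_flag(out$flags[picked$.row], "year_off_by_one", off)
  out
}

resolve_article_number <- function(mc, index) {
  mc <- mc |> mutate(.row = dplyr::row_number())
  out <- empty_entries(nrow(mc))
  out$lsid <- mc[["lsid"]] %||% rep(NA_character_, nrow(mc))

  cand <- mc |>
    filter(!is.na(.data$article_number), !is.na(.data$container)) |>
    inner_join(index$by_artno, by = c("article_number" = "token"),
               relationship = "many-to-many") |>
    filter(.data$container == .data$container_canon)
  if (nrow(cand) == 0) return(out)

  work_vol <- index$works |> select(work_id2 = "work_id", work_vol = "volume")
  picked <- cand |>
    rename(work_id2 = "work_id") |>
    left_join(work_vol, by = "work_id2") |>
    group_by(.data$.row) |>
    mutate(n_cand = dplyr::n_distinct(.data$work_id2)) |>
    arrange(.data$work_id2, .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  out$work_id[picked$.row] <- picked$work_id2
  out$method[picked$.row] <- "article_number"
  out$flags[picked$.row] <- add_flag(out$flags[picked$.row], "ambiguous",
                                     picked$n_cand > 1)
  vol_disagree <- !is.na(picked$volume) & !is.na(picked$work_vol) &
    picked$volume != picked$work_vol
  out$flags[picked$.row] <- add_flag(out$flags[picked$.row],
                                     "journal_volume_mismatch", vol_disagree)
  out
}

#' Score microcitations against works by weighted similarity
#'
#' Weighted sum: canonical container equality (0.4), exact volume match
#' (0.2), year within the window (0.2), author-block token overlap as
#' Jaccard similarity on lower-cased word tokens (0.2; two empty author sets
#' count as full overlap). Used by the full-citation fallback.
#'
#' @param mc One-row parsed microcitation tibble.
#' @param works Works tibble with a `container_canon` column.
#' @param weights Named numeric: `container`, `volume`, `year`, `authors`.
#' @param year_window Integer tolerance on year, default 1.
#' @return Numeric vector of scores in `[0, 1]`, one per work.
#' @export
citation_similarity <- function(mc, works,
                                weights = c(container = 0.4, volume = 0.2,
                                            year = 0.2, authors = 0.2),
                                year_window = 1L) {
  s_container <- !is.na(mc$container) & !is.na(works$container_canon) &
    mc$container == works$container_canon
  s_volume <- !is.na(mc$volume) & !is.na(works$volume) & mc$volume == works$volume
  s_year <- !is.na(mc$year) & !is.na(works$year) &
    abs(mc$year - works$year) <= year_window
  mc_tokens <- if (!is.na(mc$authors)) {
    unique(tolower(stringr::str_extract_all(mc$authors, "[\\p{L}]+")[[1]]))
  } else character()
  mc_tokens <- setdiff(mc_tokens, c("and", "et", "al"))
  s_auth <- purrr::map_dbl(works$authors, function(a) {
    wt <- unique(tolower(unlist(stringr::str_extract_all(a, "[\\p{L}]+"))))
    if (length(mc_tokens) == 0 && length(wt) == 0) return(1)
    u <- length(union(mc_tokens, wt))
    if (u == 0) return(0)
    length(intersect(mc_tokens, wt)) / u
  })
  weights[["container"]] * s_container + weights[["volume"]] * s_volume +
    weights[["year"]] * s_year + weights[["authors"]] * s_auth
}

resolve_full_citation <- function(mc, index, threshold = 0.8,
                                  weights = c(container = 0.4, volume = 0.2,
                                              year = 0.2, authors = 0.2),
                                  year_window = 1L) {
  out <- empty_entries(nrow(mc))
  out$lsid <- mc[["lsid"]] %||% rep(NA_character_, nrow(mc))
  works <- index$works
  if (nrow(works) == 0) return(out)
  for (i in seq_len(nrow(mc))) {
    if (is.na(mc$container[i])) next
    sc <- citation_similarity(mc[i, ], works, weights, year_window)
    best <- max(sc)
    if (best >= threshold) {
      hit <- which(sc == best)
      hit <- hit[order(works$work_id[hit])]
      out$work_id[i] <- works$work_id[hit[1]]
      out$method[i] <- "full_citation"
      out$score[i] <- best
      if (length(hit) > 1) out$flags[i] <- add_flag(out$flags[i], "ambiguous")
    }
  }
  out
}

#' Resolve microcitations against a bibliography index
#'
#' Runs the evidence cascade for each parsed microcitation: page-range
#' containment, then article-number equality, then fuzzy full-citation
#' similarity, stopping at the first success. Records that fail every path
#' are handed to [detect_mismatch()], which may attach a suggested
#' alternative work (never an accepted match). All failures are encoded as
#' `unmatched` entries; the function does not error.
#'
#' @param mc Parsed microcitation tibble ([parse_microcitation()] output),
#'   optionally carrying an `lsid` column which is propagated.
#' @param index A [build_index()] object.
#' @param threshold Full-citation similarity threshold in `[0, 1]`, default
#'   0.8.
#' @param weights Similarity weights, see [citation_similarity()].
#' @param year_window Year tolerance (publication-date vs issue-date drift),
#'   default ±1.
#' @return Mapping tibble: `lsid`, `work_id`, `method`, `flags`,
#'   `suggestion_work_id`, `score`.
#' @export
resolve_microcitation <- function(mc, index, threshold = 0.8,
                                  weights = c(container = 0.4, volume = 0.2,
                                              year = 0.2, authors = 0.2),
                                  year_window = 1L) {
  stopifnot(inherits(index, "biblio_index"))
  if (nrow(mc) == 0) return(empty_entries(0))
  out <- resolve_page_range(mc, index, year_window)
  todo <- out$method == "unmatched"
  if (any(todo)) {
    nxt <- resolve_article_number(mc[todo, , drop = FALSE], index)
    out[todo, ] <- mutate(nxt, lsid = out$lsid[todo])
    todo <- out$method == "unmatched"
  }
  if (any(todo)) {
    nxt <- resolve_full_citation(mc[todo, , drop = FALSE], index, threshold,
                                 weights, year_window)
    out[todo, ] <- mutate(nxt, lsid = out$lsid[todo])
    todo <- out$method == "unmatched"
  }
  if (any(todo)) {
    nxt <- detect_mismatch(mc[todo, , drop = FALSE], index, year_window)
    out[todo, ] <- mutate(nxt, lsid = out$lsid[todo])
  }
  out
}

#' Match a microcitation by article number alone
#'
#' The article-number path on its own: a work under the same canonical
#' container matches when its DOI's final dot-/slash-delimited token, or its
#' explicit article-number field, equals the microcitation's article number.
#' Volume disagreement does not block the match but is flagged.
#'
#' @inheritParams resolve_microcitation
#' @return Mapping tibble (method `article_number` or `unmatched`).
#' @export
match_article_number <- function(mc, index) {
  stopifnot(inherits(index, "biblio_index"))
  resolve_article_number(mc, index)
}

#' Match a microcitation by fuzzy full-citation similarity
#'
#' Scores every work with [citation_similarity()] and accepts the highest
#' scorer at or above `threshold`; ties are flagged ambiguous and broken by
#' lowest `work_id`. Deterministic given inputs.
#'
#' @inheritParams resolve_microcitation
#' @param works Works tibble or a [build_index()] object.
#' @return Mapping tibble (method `full_citation` or `unmatched`).
#' @export
match_full_citation <- function(mc, works, threshold = 0.8,
                                weights = c(container = 0.4, volume = 0.2,
                                            year = 0.2, authors = 0.2),
                                year_window = 1L) {
  index <- if (inherits(works, "biblio_index")) works else build_index(works)
  resolve_full_citation(mc, index, threshold, weights, year_window)
}

#' Diagnose journal/volume mismatches
#'
#' For microcitations that resolve to nothing under their own `(container,
#' volume)` key, searches *all* containers for works with the same volume
#' token whose page range contains the cited page (year within the window);
#' when the microcitation carries an article number instead of a page, the
#' search matches article-number tokens across containers. Exactly one
#' qualifying alternative container yields an unmatched entry flagged
#' `journal_volume_mismatch;suggested_alternative` with the suggested work;
#' several yield an `ambiguous` flag and no suggestion. A mismatch between
#' journal and volume numbers is often a clue that the source record is in
#' error, so suggestions are advisory only and never auto-accepted.
#'
#' @inheritParams resolve_microcitation
#' @return Mapping tibble; `method` is always `"unmatched"`.
#' @export
detect_mismatch <- function(mc, index, year_window = 1L) {
  stopifnot(inherits(index, "biblio_index"))
  mc <- mc |> mutate(.row = dplyr::row_number())
  out <- empty_entries(nrow(mc))
  out$lsid <- mc[["lsid"]] %||% rep(NA_character_, nrow(mc))
  works <- index$works

  cand_page <- mc |>
    filter(!is.na(.data$volume), !is.na(.data$page)) |>
    inner_join(
      works |>
        select(work_id2 = "work_id", alt_container = "container_canon",
               "volume", "page_start", "page_end", work_year = "year"),
      by = "volume", relationship = "many-to-many"
    ) |>
    filter(.data$alt_container != .data$container | is.na(.data$container),
           !is.na(.data$page_start), !is.na(.data$page_end),
           .data$page >= .data$page_start, .data$page <= .data$page_end,
           year_ok(.data$year, .data$work_year, year_window))

  cand_art <- mc |>
    filter(!is.na(.data$article_number)) |>
    inner_join(index$by_artno, by = c("article_number" = "token"),
               relationship = "many-to-many") |>
    filter(.data$container_canon != .data$container | is.na(.data$container)) |>
    rename(work_id2 = "work_id", alt_container = "container_canon")

  cand <- dplyr::bind_rows(
    cand_page |> select(".row", "work_id2", "alt_container"),
    cand_art |> select(".row", "work_id2", "alt_container")
  )
  if (nrow(cand) == 0) return(out)

  summar <- cand |>
    group_by(.data$.row) |>
    summarise(
      n_containers = dplyr::n_distinct(.data$alt_container),
      suggestion = sort(.data$work_id2)[1],
      .groups = "drop"
    )
  one <- summar |> filter(.data$n_containers == 1)
  out$flags[one$.row] <- add_flag(out$flags[one$.row], "journal_volume_mismatch")
  out$flags[one$.row] <- add_flag(out$flags[one$.row], "suggested_alternative")
  out$suggestion_work_id[one$.row] <- one$suggestion
  many <- summar |> filter(.data$n_containers > 1)
  out$flags[many$.row] <- add_flag(out$flags[many$.row], "ambiguous")
  out
}

#' Resolve a table of name records end to end
#'
#' Parses each record's raw citation string (records the parser cannot read
#' become unmatched entries rather than errors) and runs
#' [resolve_microcitation()] over the batch. Mapped identifiers are attached
#' from the matched works.
#'
#' @param names Tibble of name records ([name_records()]).
#' @param index A [build_index()] object.
#' @param ... Passed to [resolve_microcitation()].
#' @return Mapping tibble with one row per name, plus an `identifiers`
#'   list-column copied from the matched work (empty set when unmatched).
#' @export
resolve_names <- function(names, index, ...) {
  mc <- parse_microcitation(names$citation_string, aliases = index$aliases,
                            on_failure = "na")
  mc$lsid <- names$lsid
  entries <- resolve_microcitation(mc, index, ...)
  lut <- stats::setNames(index$works$identifiers, index$works$work_id)
  entries$identifiers <- purrr::map(entries$work_id, function(w) {
    if (is.na(w)) pid_set() else lut[[w]]
  })
  entries
}
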