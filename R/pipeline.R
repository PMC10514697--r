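# Pipeline: orchestrate parse -> match -> export -> report, plus a
# name-lookup convenience for interactive "cite this name" queries.

#' Default run configuration
#'
#' Matching thresholds and weights, identifier precedence,
#' authority-equivalence rules, container aliases and the year window, in
#' one list. Values can be overridden programmatically or loaded from a
#' YAML file with [read_config()].
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    precedence = default_precedence(),
    equivalence_rules = default_equivalence_rules(),
    aliases = default_aliases(),
    full_citation_threshold = 0.8,
    similarity_weights = c(container = 0.4, volume = 0.2, year = 0.2, authors = 0.2),
    year_window = 1L,
    continuous_k = 5L
  )
}

#' Read a YAML run configuration
#'
#' Recognised keys: `precedence` (character vector), `aliases` (list of
#' `alias: canonical` pairs), `equivalence_rules` (list of two-element
#' authority pairs), `full_citation_threshold`, `similarity_weights`,
#' `year_window`, `continuous_k`. Missing keys fall back to
#' [default_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  y <- yaml::read_yaml(path)
  if (!is.null(y$precedence)) cfg$precedence <- as.character(y$precedence)
  if (!is.null(y$aliases)) {
    cfg$aliases <- tibble(alias = names(y$aliases),
                          canonical = unlist(y$aliases, use.names = FALSE))
  }
  if (!is.null(y$equivalence_rules)) {
    cfg$equivalence_rules <- dplyr::bind_rows(purrr::map(y$equivalence_rules, function(r) {
      tibble(authority_a = r[[1]], authority_b = r[[2]])
    }))
  }
  for (k in c("full_citation_threshold", "year_window", "continuous_k")) {
    if (!is.null(y[[k]])) cfg[[k]] <- y[[k]]
  }
  if (!is.null(y$similarity_weights)) cfg$similarity_weights <- unlist(y$similarity_weights)
  stopifnot(cfg$full_citation_threshold >= 0, cfg$full_citation_threshold <= 1,
            cfg$year_window >= 0)
  cfg
}

#' Run the full linking pipeline
#'
#' Parses the name records' citation strings, resolves them against the
#' bibliography, and (when `out_dir` is given) writes the mapping TSV, the
#' CoLDP package, the N-Triples file for DOI-bearing names and a coverage
#' report. Every flagged record is surfaced as a warning-level log line:
#' links between databases attract scrutiny, so diagnostics are first-class
#' output.
#'
#' @param names Tibble of name records ([name_records()] /
#'   [read_names_tsv()]).
#' @param works Tibble of works ([works_tbl()] / [read_biblio()]).
#' @param config Configuration list, [default_config()] by default.
#' @param out_dir Optional output directory.
#' @param verbose Emit per-record log lines for flagged records.
#' @return A `taxolink_run` object: list with `entries`, `names`, `works`,
#'   `summary`, `paths`. Use [generics::tidy()] for the per-name mapping and
#'   [generics::glance()] for the one-row summary.
#' @export
run_linking <- function(names, works, config = default_config(), out_dir = NULL,
                        verbose = FALSE) {
  index <- build_index(works, aliases = config$aliases,
                       continuous_k = config$continuous_k)
  entries <- resolve_names(
    names, index,
    threshold = config$full_citation_threshold,
    weights = config$similarity_weights,
    year_window = config$year_window
  )
  if (verbose) {
    flagged <- entries |> filter(nzchar(.data$flags))
    for (i in seq_len(nrow(flagged))) {
      message(sprintf("[match] %s outcome=%s flags=%s", flagged$lsid[i],
                      flagged$method[i], flagged$flags[i]))
    }
  }
  method_counts <- entries |>
    count(.data$method) |>
    tidyr::pivot_wider(names_from = "method", values_from = "n")
  if (nrow(method_counts) == 0) method_counts <- tibble(.rows = 1L)
  summary <- method_counts |>
    mutate(
      total = nrow(entries),
      matched = sum(!is.na(entries$work_id)),
      unmatched = sum(is.na(entries$work_id)),
      flagged = sum(nzchar(entries$flags))
    )
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mapping <- entries |>
      mutate(identifiers = purrr::map_chr(.data$identifiers, function(ids) {
        if (is.null(ids) || nrow(ids) == 0) ""
        else paste(paste0(ids$kind, ":", ids$value), collapse = "|")
      }))
    paths$mapping <- file.path(out_dir, "mapping.tsv")
    readr::write_tsv(mapping, paths$mapping, na = "")
    paths$coldp <- file.path(out_dir, "coldp")
    write_coldp(entries, names, works, paths$coldp)
    doi <- work_doi(works$identifiers)
    wlut <- stats::setNames(seq_len(nrow(works)), works$work_id)
    with_doi <- entries |> filter(!is.na(.data$work_id)) |>
      filter(!is.na(doi[wlut[.data$work_id]]))
    paths$ntriples <- file.path(out_dir, "names.nt")
    if (nrow(with_doi)) {
      nm <- names[match(with_doi$lsid, names$lsid), ]
      wk <- works[wlut[with_doi$work_id], ]
      write_ntriples(name_to_triples(nm, wk), paths$ntriples)
    } else {
      writeLines(character(), paths$ntriples)
    }
    counts <- summarize_by_identifier(entries, names)
    paths$coverage <- file.path(out_dir, "coverage.tsv")
    readr::write_tsv(counts, paths$coverage, na = "")
  }
  structure(list(entries = entries, names = names, works = works,
                 summary = summary, paths = paths),
            class = "taxolink_run")
}

#' @export
print.taxolink_run <- function(x, ...) {
  s <- x$summary
  cat("<taxolink_run> ", s$total, " names: ", s$matched, " matched, ",
      s$unmatched, " unmatched, ", s$flagged, " flagged\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-name mapping table of a linking run
#'
#' @param x A `taxolink_run` object.
#' @param ... Ignored.
#' @return The mapping tibble (`lsid`, `work_id`, `method`, `flags`,
#'   `suggestion_work_id`, `score`, `identifiers`).
#' @exportS3Method generics::tidy
tidy.taxolink_run <- function(x, ...) {
  as_tibble(x$entries)
}

#' One-row summary of a linking run
#'
#' @param x A `taxolink_run` object.
#' @param ... Ignored.
#' @return One-row tibble with totals, per-method counts and the flagged
#'   count.
#' @exportS3Method generics::glance
glance.taxolink_run <- function(x, ...) {
  as_tibble(x$summary)
}

#' Method-mix plot for a linking run
#'
#' @param object A `taxolink_run` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.taxolink_run <- function(object, ...) {
  df <- object$entries |> count(.data$method)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$method, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "names", title = "Resolution methods") +
    ggplot2::theme_minimal()
}

#' Look up a taxonomic name in a completed mapping
#'
#' Exact match on the name string (case-insensitive, whitespace-normalized)
#' against the mapping produced by [run_linking()]. Returns, per matching
#' record (homonyms may yield several), the persistent identifiers ordered
#' by precedence — DOI or Wikidata item first when present — and a
#' formatted citation of the publishing work.
#'
#' @param run A `taxolink_run` object.
#' @param query Name string.
#' @param precedence Identifier precedence, [default_precedence()] plus
#'   Wikidata by default.
#' @return Tibble `lsid`, `name_string`, `work_id`, `identifier_kind`,
#'   `identifier`, `citation`, ordered by precedence within each record;
#'   raises a `taxolink_not_found` condition when the name is absent.
#' @export
lookup_name <- function(run, query, precedence = c(default_precedence(), "WikidataQID")) {
  stopifnot(inherits(run, "taxolink_run"))
  key <- tolower(stringr::str_squish(query))
  hits <- run$names |> filter(tolower(stringr::str_squish(.data$name_string)) == key)
  if (nrow(hits) == 0) {
    abort(paste0("Name not found: ", query), class = "taxolink_not_found")
  }
  wlut <- stats::setNames(seq_len(nrow(run$works)), run$works$work_id)
  ent <- run$entries[match(hits$lsid, run$entries$lsid), ]
  purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    ids <- ent$identifiers[[i]]
    wid <- ent$work_id[i]
    cite <- if (!is.na(wid)) format_citation(run$works[wlut[wid], ]) else NA_character_
    if (is.null(ids) || nrow(ids) == 0) {
      return(tibble(lsid = hits$lsid[i], name_string = hits$name_string[i],
                    work_id = wid, identifier_kind = NA_character_,
                    identifier = NA_character_, citation = cite))
    }
    rank <- match(ids$kind, precedence)
    rank[is.na(rank)] <- length(precedence) + 1L
    ids <- ids[order(rank, ids$value), ]
    tibble(lsid = hits$lsid[i], name_string = hits$name_string[i], work_id = wid,
           identifier_kind = ids$kind, identifier = ids$value, citation = cite)
  })
}
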