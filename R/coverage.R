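# Coverage statistics: identifier-kind counts per source database, the
# overall coverage percentage, decade x container name densities with
# modal-decade ordering, and long-tail cumulative curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

COUNT_STATISTICS <- c("TotalNames", "NamesWithPublications", PID_KINDS, "Any")

#' Sum per-source identifier counts into a totals column
#'
#' The totalling logic behind the summary table: given per-source counts in
#' long form (`source`, `statistic`, `count`), appends a `Total` source whose
#' cells are the row sums across sources. Kept separate from
#' [summarize_by_identifier()] so pre-counted cells (for example a published
#' summary table) can be totalled directly.
#'
#' @param counts Tibble `source`, `statistic`, `count` without a `Total`
#'   source.
#' @return The input plus `Total` rows, statistics ordered as in the
#'   summary table.
#' @export
counts_add_totals <- function(counts) {
  stopifnot(all(c("source", "statistic", "count") %in% names(counts)))
  counts <- counts |> filter(.data$source != "Total")
  totals <- counts |>
    group_by(.data$statistic) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(source = "Total")
  dplyr::bind_rows(counts, totals) |>
    mutate(statistic = factor(.data$statistic,
                              levels = union(COUNT_STATISTICS, unique(.data$statistic)))) |>
    arrange(.data$statistic, .data$source) |>
    mutate(statistic = as.character(.data$statistic))
}

#' Count names and identifier kinds per source database
#'
#' For each source: the total number of names, how many carry publication
#' information (a parseable or non-empty citation string), per-kind counts
#' of mapped identifiers (a name counts once for every kind it has), and an
#' `Any` row counting names with at least one identifier of any kind. A
#' `Total` source column of row sums is appended via [counts_add_totals()].
#'
#' @param entries Mapping tibble from [resolve_names()] (needs the
#'   `identifiers` list-column).
#' @param names Tibble of name records with `source_db`.
#' @return Long-form counts tibble: `source`, `statistic`, `count`.
#' @export
summarize_by_identifier <- function(entries, names) {
  joined <- names |>
    select("lsid", "source_db", "citation_string") |>
    left_join(entries |> select("lsid", "identifiers"), by = "lsid")
  base <- joined |>
    group_by(source = .data$source_db) |>
    summarise(
      TotalNames = dplyr::n(),
      NamesWithPublications = sum(!is.na(.data$citation_string) &
                                    nzchar(.data$citation_string)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"source", names_to = "statistic", values_to = "count")
  kinds <- joined |>
    mutate(kinds = purrr::map(.data$identifiers, function(ids) {
      if (is.null(ids)) character() else unique(ids$kind)
    })) |>
    select("source_db", "kinds") |>
    tidyr::unnest_longer("kinds", values_to = "kind") |>
    count(source = .data$source_db, statistic = as.character(.data$kind),
          name = "count")
  any_row <- joined |>
    mutate(has_any = purrr::map_lgl(.data$identifiers,
                                    function(ids) !is.null(ids) && nrow(ids) > 0)) |>
    group_by(source = .data$source_db) |>
    summarise(count = sum(.data$has_any), .groups = "drop") |>
    mutate(statistic = "Any")
  all_sources <- unique(names$source_db)
  grid <- tidyr::expand_grid(source = all_sources, statistic = COUNT_STATISTICS)
  long <- dplyr::bind_rows(base, kinds, any_row) |>
    right_join(grid, by = c("source", "statistic")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L))
  counts_add_totals(long)
}

#' Per-source identifier counts for the three nomenclator mappings
#'
#' The per-database cells of the published linking summary for Index
#' Fungorum, IPNI and ION: total names, names with publication information,
#' and names whose publication was mapped to each identifier kind (plus the
#' `Any` row). Shipped as plain TSV in `extdata`; the totals column is
#' never stored — recompute it with [counts_add_totals()].
#'
#' @return Long-form counts tibble `source`, `statistic`, `count` (no
#'   `Total` rows).
#' @export
reported_source_counts <- function() {
  path <- system.file("extdata", "source_counts.tsv", package = "taxolink")
  readr::read_tsv(path, col_types = "cci")
}

#' Overall identifier coverage percentage
#'
#' `100 * Any / NamesWithPublications` over the totals column: the share of
#' names with publication information whose publication has been mapped to
#' at least one persistent identifier.
#'
#' @param counts Long-form counts tibble from [summarize_by_identifier()] or
#'   [counts_add_totals()].
#' @return A single percentage in `[0, 100]`.
#' @export
coverage_percentage <- function(counts) {
  tot <- counts |> filter(.data$source == "Total")
  any_n <- tot$count[tot$statistic == "Any"]
  pub_n <- tot$count[tot$statistic == "NamesWithPublications"]
  if (length(pub_n) == 0 || pub_n == 0) {
    abort("NamesWithPublications total is zero", class = "taxolink_division_by_zero")
  }
  100 * any_n / pub_n
}

decade_of <- function(year) as.integer(floor(year / 10) * 10)

#' Decade-by-container name density matrix
#'
#' Selects the `top_k` containers by total dated names, bins their names
#' into 10-year left-closed decades over `year_range` (out-of-range names
#' go to an explicit `"other"` bucket rather than being dropped), orders
#' containers by their modal decade — the decade with the most names; ties
#' broken by earlier decade, then by larger total — and attaches each
#' container's persistent-identifier percentage (share of its names that
#' were mapped to at least one identifier). Undated names are excluded from
#' the matrix.
#'
#' @param names Name records with a `year` and `container` column (e.g.
#'   from joining parsed microcitations back on).
#' @param entries Optional mapping tibble; enables the PID percentage.
#' @param top_k Number of containers, default 50.
#' @param year_range Length-2 integer vector, default `c(1750, 2020)`.
#' @return Tibble `container`, `decade`, `n` with attributes
#'   `container_order` (modal-decade ordering) and `pid_percentage`
#'   (per-container tibble). Class `taxolink_decades`.
#' @export
decade_container_matrix <- function(names, entries = NULL, top_k = 50,
                                    year_range = c(1750, 2020)) {
  stopifnot(top_k >= 1)
  dated <- names |> filter(!is.na(.data$year), !is.na(.data$container))
  top <- dated |> count(.data$container, sort = TRUE) |>
    slice_head(n = top_k) |> pull(.data$container)
  binned <- dated |>
    filter(.data$container %in% top) |>
    mutate(decade = dplyr::if_else(
      .data$year >= year_range[1] & .data$year < year_range[2] + 10,
      as.character(decade_of(.data$year)), "other"
    )) |>
    count(.data$container, .data$decade, name = "n")
  ord <- binned |>
    filter(.data$decade != "other") |>
    group_by(.data$container) |>
    summarise(
      modal_decade = {
        mx <- max(.data$n)
        min(as.integer(.data$decade[.data$n == mx]))
      },
      total = sum(.data$n), .groups = "drop"
    ) |>
    arrange(.data$modal_decade, dplyr::desc(.data$total), .data$container)
  pid <- NULL
  if (!is.null(entries)) {
    pid <- names |>
      filter(.data$container %in% top) |>
      left_join(entries |> select("lsid", "identifiers"), by = "lsid") |>
      group_by(.data$container) |>
      summarise(
        pid_percentage = 100 * mean(purrr::map_lgl(
          .data$identifiers, function(ids) !is.null(ids) && nrow(ids) > 0
        )),
        .groups = "drop"
      )
  }
  structure(binned,
            container_order = ord,
            pid_percentage = pid,
            class = c("taxolink_decades", class(binned)))
}

#' Long-tail cumulative curve of names per container
#'
#' Ranks containers in descending order of the number of names each
#' publishes (ties broken lexicographically) and computes, for the top
#' `top_n`, the cumulative percentage of *all* names in the corpus — not
#' just the displayed top — added by each rank.
#'
#' @param names Name records with a `container` column.
#' @param top_n Number of ranked containers to keep, default 100.
#' @return Tibble `rank`, `container`, `n_names`, `cumulative_pct`; class
#'   `taxolink_longtail`.
#' @export
long_tail_curve <- function(names, top_n = 100) {
  stopifnot(top_n >= 1)
  total <- nrow(names)
  out <- names |>
    filter(!is.na(.data$container)) |>
    count(.data$container, name = "n_names") |>
    arrange(dplyr::desc(.data$n_names), .data$container) |>
    slice_head(n = top_n) |>
    mutate(rank = dplyr::row_number(),
           cumulative_pct = 100 * cumsum(.data$n_names) / total) |>
    select("rank", "container", "n_names", "cumulative_pct")
  structure(out, class = c("taxolink_longtail", class(out)))
}

#' @rdname decade_container_matrix
#' @param object A `taxolink_decades` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.taxolink_decades <- function(object, ...) {
  ord <- attr(object, "container_order")
  df <- as_tibble(object) |>
    filter(.data$decade != "other") |>
    mutate(
      container = factor(.data$container, levels = rev(ord$container)),
      decade = as.integer(.data$decade)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decade, y = .data$container,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "names") +
    ggplot2::labs(x = "decade", y = NULL,
                  title = "Names per decade by publication venue") +
    ggplot2::theme_minimal()
}

#' @rdname long_tail_curve
#' @param object A `taxolink_longtail` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.taxolink_longtail <- function(object, ...) {
  df <- as_tibble(object)
  scale <- max(df$n_names) / 100
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_names), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_pct * scale),
                       colour = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "names per venue",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "cumulative % of all names")
    ) +
    ggplot2::labs(x = "venue rank", title = "Long tail of name-publishing venues") +
    ggplot2::theme_minimal()
}
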