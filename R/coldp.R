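# CoLDP export: serialize the name -> literature mapping as a Catalogue of
# Life Data Package (delimited-text checklist with a names table and a
# references table), and read it back for round-trip verification.

sanitize_token <- function(x) {
  gsub("-+", "-", gsub("[^A-Za-z0-9-]", "-", x))
}

#' Assign a CoLDP reference identifier to a work
#'
#' CoLDP requires a unique identifier per bibliographic reference. The rule:
#' the Wikidata QID when the work has one; otherwise an identifier derived
#' from the preferred persistent identifier — for a DOI,
#' `"doi-"` + the DOI with `/` and `.` replaced by `-`; for other kinds, the
#' lower-cased kind, a dash, and the sanitized value. Deterministic, and
#' injective as long as distinct works carry distinct identifiers.
#'
#' @param works Tibble of works (each must carry at least one identifier).
#' @param precedence Identifier precedence for the non-QID fallback.
#' @return Character vector of reference identifiers, one per work.
#' @examples
#' w <- works_tbl("w1", "MycoKeys", volume = "83", year = 2021,
#'                identifiers = pid_set(doi = "10.3897/mycokeys.83.72325"))
#' assign_reference_id(w)
#' @export
assign_reference_id <- function(works, precedence = default_precedence()) {
  purrr::map_chr(works$identifiers, function(ids) {
    if (is.null(ids) || nrow(ids) == 0) {
      abort("Work has no identifiers; cannot assign a reference id",
            class = "taxolink_no_identifier")
    }
    qid <- ids$value[ids$kind == "WikidataQID"]
    if (length(qid)) return(sort(qid)[1])
    pref <- preferred_identifier(ids, precedence)
    if (pref$kind == "DOI") {
      paste0("doi-", gsub("[/.]", "-", pref$value))
    } else {
      paste0(tolower(pref$kind), "-", sanitize_token(pref$value))
    }
  })
}

#' Write the mapping as a CoLDP-style checklist package
#'
#' Emits `names.tsv` (ID = serialized LSID, scientificName, rank,
#' referenceID, page), `references.tsv` (ID, citation, DOI, link, remarks)
#' and `metadata.yaml` into `out_dir`. Only matched entries enter the
#' package — the published datasets comprise the subset of names mapped to
#' at least one persistent identifier — while unmatched names go to a
#' sidecar `unmapped.tsv` for audit. Shared works are deduplicated; rows are
#' ordered (names by LSID, references by reference id) so identical inputs
#' produce byte-identical tables. UTF-8, LF line endings.
#'
#' @param entries Mapping tibble from [resolve_names()].
#' @param names Tibble of name records.
#' @param works Tibble of works.
#' @param out_dir Output directory (created if needed).
#' @param title Dataset title for the metadata file.
#' @return Invisibly, a list with `names` and `references` tibbles as
#'   written.
#' @export
write_coldp <- function(entries, names, works, out_dir,
                        title = "Taxonomic names mapped to literature identifiers") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  matched <- entries |> filter(!is.na(.data$work_id))
  dangling <- setdiff(matched$work_id, works$work_id)
  if (length(dangling)) {
    abort(paste0("Mapping refers to unknown work_id: ",
                 paste(utils::head(dangling, 3), collapse = ", ")),
          class = "taxolink_dangling_work")
  }
  # the package holds only names mapped to >= 1 persistent identifier;
  # matches to identifier-less works are auditable, not publishable
  n_ids <- stats::setNames(purrr::map_int(works$identifiers,
                                          function(ids) if (is.null(ids)) 0L else nrow(ids)),
                           works$work_id)
  matched <- matched |> filter(n_ids[.data$work_id] > 0)
  used <- works |> filter(.data$work_id %in% matched$work_id)
  ref_ids <- if (nrow(used)) assign_reference_id(used) else character()
  refs <- tibble(
    ID = ref_ids,
    citation = purrr::map_chr(seq_len(nrow(used)), function(i) format_citation(used[i, ])),
    DOI = work_doi(used$identifiers),
    link = purrr::map_chr(used$identifiers, function(ids) {
      non_doi <- ids |> filter(!.data$kind %in% c("DOI", "WikidataQID"))
      if (nrow(non_doi)) preferred_identifier(non_doi)$value else NA_character_
    }),
    remarks = NA_character_,
    work_id = used$work_id
  )
  ref_lut <- stats::setNames(refs$ID, refs$work_id)
  refs <- refs |>
    distinct(.data$ID, .keep_all = TRUE) |>
    arrange(.data$ID)
  mc <- parse_microcitation(names$citation_string, on_failure = "na")
  page_lut <- stats::setNames(mc$page, names$lsid)
  name_lut <- stats::setNames(names$name_string, names$lsid)
  rank_lut <- stats::setNames(names$rank, names$lsid)

  names_out <- matched |>
    transmute(
      ID = .data$lsid,
      scientificName = unname(name_lut[.data$lsid]),
      rank = unname(rank_lut[.data$lsid]),
      referenceID = unname(ref_lut[.data$work_id]),
      page = unname(page_lut[.data$lsid])
    ) |>
    arrange(.data$ID)

  publishable <- !is.na(entries$work_id) &
    tidyr::replace_na(unname(n_ids[entries$work_id]) > 0, FALSE)
  unmapped <- entries[!publishable, ] |>
    transmute(ID = .data$lsid,
              scientificName = unname(name_lut[.data$lsid]),
              flags = .data$flags,
              suggestion_work_id = .data$suggestion_work_id) |>
    arrange(.data$ID)

  refs_out <- refs |> select(-"work_id")
  readr::write_tsv(names_out, file.path(out_dir, "names.tsv"), na = "")
  readr::write_tsv(refs_out, file.path(out_dir, "references.tsv"), na = "")
  readr::write_tsv(unmapped, file.path(out_dir, "unmapped.tsv"), na = "")
  meta <- list(
    title = title,
    description = "Mapping between taxonomic name identifiers (LSIDs) and work-level bibliographic identifiers.",
    version = as.character(utils::packageVersion("taxolink")),
    format = "CoLDP"
  )
  yaml::write_yaml(meta, file.path(out_dir, "metadata.yaml"))
  invisible(list(names = names_out, references = refs_out))
}

#' Read a CoLDP-style package written by [write_coldp()]
#'
#' Verifies referential integrity: every `referenceID` cited by a name row
#' must exist in the references table.
#'
#' @param dir Package directory.
#' @return List with tibbles `names` and `references`.
#' @export
read_coldp <- function(dir) {
  np <- file.path(dir, "names.tsv")
  rp <- file.path(dir, "references.tsv")
  if (!file.exists(np) || !file.exists(rp)) {
    abort("Not a CoLDP package directory (names.tsv / references.tsv missing)")
  }
  nm <- readr::read_tsv(np, col_types = readr::cols(.default = readr::col_character()))
  rf <- readr::read_tsv(rp, col_types = readr::cols(.default = readr::col_character()))
  orphans <- setdiff(nm$referenceID, rf$ID)
  orphans <- orphans[!is.na(orphans)]
  if (length(orphans)) {
    abort(paste0("names.tsv cites reference id(s) missing from references.tsv: ",
                 paste(utils::head(orphans, 3), collapse = ", ")),
          class = "taxolink_referential_integrity")
  }
  list(names = nm, references = rf)
}
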