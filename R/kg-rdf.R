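# Knowledge-graph export: N-Triples serialization of the name -> publication
# mapping (schema.org vocabulary, Bioschemas TaxonName profile), cleaning of
# ORCID-style person records, graph assembly and the affiliation join query.

#' Vocabulary IRIs used in the RDF export
#'
#' One constants table so the vocabulary is swappable: schema.org classes
#' and properties for taxon names, people and organisations, plus rdf:type.
#' Authorship is expressed work-centrically as
#' `(work DOI IRI, schema:creator, person IRI)`.
#'
#' @return Named character vector of IRIs.
#' @export
kg_vocabulary <- function() {
  c(
    type        = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
    TaxonName   = "https://schema.org/TaxonName",
    Person      = "https://schema.org/Person",
    Organization = "https://schema.org/Organization",
    name        = "https://schema.org/name",
    isBasedOn   = "https://schema.org/isBasedOn",
    affiliation = "https://schema.org/affiliation",
    creator     = "https://schema.org/creator",
    givenName   = "https://schema.org/givenName",
    familyName  = "https://schema.org/familyName"
  )
}

doi_iri <- function(doi) paste0("https://doi.org/", doi)

#' Construct a triple table
#'
#' Triples are held as a tibble: `subject` and `predicate` are absolute IRIs
#' or URNs (never literals); `object` is an IRI/URN when `object_iri` is
#' `TRUE`, otherwise a plain literal.
#'
#' @param subject,predicate,object Character vectors.
#' @param object_iri Logical vector; is `object` an IRI?
#' @return Triple tibble.
#' @export
triples <- function(subject = character(), predicate = character(),
                    object = character(), object_iri = logical()) {
  tibble(subject = subject, predicate = predicate,
         object = object, object_iri = object_iri)
}

#' Express a name-to-publication link as RDF triples
#'
#' Restricted to names whose publication has a DOI — the DOI is the
#' identifier most likely to occur in other datasets (ORCID, Wikidata), so
#' DOI-less links add nothing joinable. Each DOI-bearing name yields exactly
#' three triples: the LSID is typed as a taxon name, labelled with the name
#' string, and linked to the DOI IRI with `schema:isBasedOn`.
#'
#' @param names Tibble of name records.
#' @param works Tibble of works, matched 1:1 to `names` rows (recycled if a
#'   single row).
#' @return Triple tibble with `3 * nrow(names)` rows.
#' @export
name_to_triples <- function(names, works) {
  v <- kg_vocabulary()
  if (nrow(works) == 1 && nrow(names) > 1) {
    works <- works[rep(1, nrow(names)), ]
  }
  stopifnot(nrow(names) == nrow(works))
  doi <- work_doi(works$identifiers)
  if (any(is.na(doi))) {
    abort("Every work must carry a DOI for RDF export; filter DOI-less works first",
          class = "taxolink_no_doi")
  }
  dplyr::bind_rows(
    triples(names$lsid, v[["type"]], rep(v[["TaxonName"]], nrow(names)),
            rep(TRUE, nrow(names))),
    triples(names$lsid, v[["name"]], names$name_string, rep(FALSE, nrow(names))),
    triples(names$lsid, v[["isBasedOn"]], doi_iri(doi), rep(TRUE, nrow(names)))
  ) |>
    arrange(.data$subject, .data$predicate, .data$object)
}

#' Clean a loosely structured ORCID-style person record
#'
#' ORCID data are user-supplied and messy; malformed URLs break triple
#' stores. Cleaning trims whitespace and control characters from IRIs,
#' repairs a missing scheme (`orcid.org/...` and `doi.org/...` gain
#' `https://`), normalizes DOIs, and drops individual fields that remain
#' invalid. The record is rejected (condition class
#' `taxolink_rejection`) only when the ORCID itself is unrecoverable
#' (`reason = "bad-orcid"`) or the record is empty (`"empty-record"`).
#'
#' @param raw A list with fields `orcid`, optional `given`, `family`,
#'   `affiliations` (list of lists with `org_name`, `scheme`, `value`), and
#'   `works` (character vector of DOI-ish strings).
#' @return A cleaned list of the same shape with `orcid` as a canonical
#'   `https://orcid.org/...` IRI and `works` as bare normalized DOIs.
#' @export
clean_person_record <- function(raw) {
  if (is.null(raw) || length(raw) == 0) {
    abort("Empty person record", class = c("taxolink_rejection"), reason = "empty-record")
  }
  scrub <- function(x) stringr::str_trim(gsub("[[:cntrl:]]", "", x))
  orcid <- scrub(raw$orcid %||% "")
  orcid <- sub("^orcid\\.org/", "https://orcid.org/", orcid)
  orcid <- sub("^http://orcid\\.org/", "https://orcid.org/", orcid)
  if (!grepl("^https://orcid\\.org/[0-9]{4}-[0-9]{4}-[0-9]{4}-[0-9]{3}[0-9X]$", orcid)) {
    abort(paste0("Unrecoverable ORCID: \"", raw$orcid %||% "", "\""),
          class = c("taxolink_rejection"), reason = "bad-orcid")
  }
  works <- purrr::map_chr(as.character(raw$works %||% character()), function(w) {
    w <- scrub(w)
    w <- sub("^(https?://)?(dx\\.)?doi\\.org/", "", w)
    out <- tryCatch(normalize_doi(w), error = function(e) NA_character_)
    out
  })
  works <- works[!is.na(works)]
  affiliations <- purrr::keep(raw$affiliations %||% list(), function(a) {
    !is.null(a$scheme) && !is.null(a$value) && nzchar(scrub(a$value))
  })
  affiliations <- purrr::map(affiliations, function(a) {
    list(org_name = scrub(a$org_name %||% ""), scheme = scrub(a$scheme),
         value = scrub(a$value))
  })
  list(
    orcid = orcid,
    given = scrub(raw$given %||% ""),
    family = scrub(raw$family %||% ""),
    affiliations = affiliations,
    works = works
  )
}

org_iri <- function(scheme, value) paste0("urn:org:", scheme, ":", value)

#' Express a person record as RDF triples
#'
#' Emits a `schema:Person` type triple, one `schema:name` literal, one
#' `schema:affiliation` triple per organisation (organisation nodes are
#' deterministic `urn:org:{scheme}:{value}` IRIs, so two people sharing an
#' organisation share the node), and one authorship triple
#' `(doi IRI, schema:creator, person)` per work DOI.
#'
#' @param p A cleaned person record from [clean_person_record()].
#' @return Triple tibble.
#' @export
person_to_triples <- function(p) {
  v <- kg_vocabulary()
  full_name <- stringr::str_squish(paste(p$given, p$family))
  out <- triples(
    subject = c(p$orcid, p$orcid),
    predicate = c(v[["type"]], v[["name"]]),
    object = c(v[["Person"]], full_name),
    object_iri = c(TRUE, FALSE)
  )
  for (a in p$affiliations) {
    out <- dplyr::bind_rows(out, triples(p$orcid, v[["affiliation"]],
                                         org_iri(a$scheme, a$value), TRUE))
  }
  if (length(p$works)) {
    out <- dplyr::bind_rows(out, triples(doi_iri(p$works), rep(v[["creator"]], length(p$works)),
                                         rep(p$orcid, length(p$works)),
                                         rep(TRUE, length(p$works))))
  }
  out
}

escape_literal <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  gsub("\t", "\\\\t", x)
}

#' Serialize triples to an N-Triples file
#'
#' @param tr Triple tibble (see [triples()]).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_ntriples <- function(tr, path) {
  obj <- ifelse(tr$object_iri,
                paste0("<", tr$object, ">"),
                paste0("\"", escape_literal(tr$object), "\""))
  lines <- paste0("<", tr$subject, "> <", tr$predicate, "> ", obj, " .")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Parse an N-Triples file
#'
#' Supports IRI subjects/objects and plain/typed/language-tagged literals;
#' malformed lines raise a parse error naming the line number.
#'
#' @param path N-Triples file.
#' @return Triple tibble.
#' @export
read_ntriples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(stringr::str_trim(lines)) & !startsWith(stringr::str_trim(lines), "#")
  idx <- which(keep)
  pat <- paste0(
    "^<([^>]*)>\\s+<([^>]*)>\\s+",
    "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<[^>]*>|@[A-Za-z-]+)?)",
    "\\s*\\.\\s*$"
  )
  m <- stringr::str_match(lines[idx], pat)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0("Malformed N-Triples at line ", idx[which(bad)[1]], " of ", path),
          class = "taxolink_ntriples_parse")
  }
  # group 4 = IRI object, group 5 = literal body
  obj_is_iri <- !is.na(m[, 4])
  unescape <- function(x) {
    x <- gsub("\\\\t", "\t", x)
    x <- gsub("\\\\n", "\n", x)
    x <- gsub("\\\\r", "\r", x)
    x <- gsub("\\\\\"", "\"", x)
    gsub("\\\\\\\\", "\\\\", x)
  }
  tibble(
    subject = m[, 2],
    predicate = m[, 3],
    object = ifelse(obj_is_iri, m[, 4], unescape(m[, 5])),
    object_iri = obj_is_iri
  )
}

#' Assemble a graph from N-Triples files
#'
#' Reads each file and unions the triples under set semantics: the graph
#' size is the number of distinct triples across all files.
#'
#' @param paths Character vector of N-Triples file paths.
#' @return Triple tibble of distinct triples, class `kg_graph`.
#' @export
assemble_graph <- function(paths) {
  tr <- lapply(paths, read_ntriples) |> dplyr::bind_rows() |> distinct()
  class(tr) <- c("kg_graph", class(tr))
  tr
}

#' Find authors at an organisation who published taxon names
#'
#' The affiliation join: taxon name `isBasedOn` work, work `creator` person,
#' person `affiliation` organisation. Given an organisation identifier
#' (e.g. RINGGOLD 41803), returns the people affiliated with it who
#' authored a work on which some taxon name is based; `lsid_authority`
#' optionally restricts the names to one database's LSID authority (e.g.
#' `"ipni.org"` for plant names).
#'
#' @param g Triple tibble from [assemble_graph()].
#' @param org_scheme,org_value Organisation identifier scheme and value.
#' @param lsid_authority Optional authority domain filter.
#' @return Tibble with columns `person` (IRI) and `name` (literal, `NA` when
#'   the graph has no name for the person).
#' @export
query_org_authors <- function(g, org_scheme, org_value, lsid_authority = NULL) {
  v <- kg_vocabulary()
  org <- org_iri(org_scheme, org_value)
  based <- g |> filter(.data$predicate == v[["isBasedOn"]]) |>
    select(lsid = "subject", work = "object")
  if (!is.null(lsid_authority)) {
    based <- based |>
      filter(startsWith(.data$lsid, paste0("urn:lsid:", tolower(lsid_authority), ":")))
  }
  authored <- g |> filter(.data$predicate == v[["creator"]]) |>
    select(work = "subject", person = "object")
  affil <- g |> filter(.data$predicate == v[["affiliation"]], .data$object == org) |>
    select(person = "subject")
  labels <- g |> filter(.data$predicate == v[["name"]], .data$object_iri == FALSE) |>
    select(person = "subject", name = "object")
  based |>
    inner_join(authored, by = "work") |>
    inner_join(affil, by = "person") |>
    left_join(labels, by = "person") |>
    distinct(.data$person, .data$name) |>
    arrange(.data$person)
}
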