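#' Default identifier precedence
#'
#' The order in which work-level identifier kinds are preferred when a work
#' carries several: DOI first (the most citable and most interlinked kind),
#' then Handle, JSTOR, BioStor, BHL, generic URL and PDF link. Wikidata QIDs
#' are reported in parallel rather than ranked against the work-level kinds.
#'
#' @return Character vector of identifier kinds.
#' @export
default_precedence <- function() {
  c("DOI", "Handle", "JSTOR", "BioStor", "BHL", "URL", "PDF")
}

#' Parse Life Science Identifiers
#'
#' LSIDs are URN-style persistent identifiers of the form
#' `urn:lsid:{authority}:{namespace}:{object_id}[:{revision}]`, used by
#' taxonomic name databases such as Index Fungorum, IPNI and ION. The
#' authority (a domain name) is case-folded to lower case on parse; the other
#' components are preserved verbatim so that [format_lsid()] round-trips.
#'
#' @param text Character vector of LSID strings.
#' @return A tibble with one row per input and columns `authority`,
#'   `namespace`, `object_id`, `revision` (`NA` when absent).
#' @examples
#' parse_lsid("urn:lsid:indexfungorum.org:names:839249")
#' @export
parse_lsid <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 0) {
    return(tibble(authority = character(), namespace = character(),
                  object_id = character(), revision = character()))
  }
  if (any(is.na(text) | !nzchar(text))) {
    abort("LSID text must be non-empty", class = "taxolink_malformed_identifier")
  }
  m <- stringr::str_match(
    text,
    "^urn:lsid:([^:]+):([^:]+):([^:]+)(?::([^:]+))?$"
  )
  bad <- is.na(m[, 1]) | !stringr::str_detect(text, stringr::regex("^urn:lsid:", ignore_case = TRUE))
  # case-insensitive scheme: retry with folded prefix
  if (any(is.na(m[, 1]))) {
    retry <- is.na(m[, 1])
    m2 <- stringr::str_match(
      text[retry],
      stringr::regex("^urn:lsid:([^:]+):([^:]+):([^:]+)(?::([^:]+))?$", ignore_case = TRUE)
    )
    m[retry, ] <- m2
  }
  if (any(is.na(m[, 1]))) {
    abort(
      paste0("Malformed LSID: ", paste(utils::head(text[is.na(m[, 1])], 3), collapse = ", ")),
      class = "taxolink_malformed_identifier"
    )
  }
  tibble(
    authority = tolower(m[, 2]),
    namespace = m[, 3],
    object_id = m[, 4],
    revision = m[, 5]
  )
}

#' Serialize parsed LSIDs
#'
#' @param lsid A tibble as returned by [parse_lsid()].
#' @return Character vector of `urn:lsid:` strings.
#' @export
format_lsid <- function(lsid) {
  out <- paste("urn:lsid", lsid$authority, lsid$namespace, lsid$object_id, sep = ":")
  has_rev <- !is.na(lsid$revision)
  out[has_rev] <- paste(out[has_rev], lsid$revision[has_rev], sep = ":")
  out
}

#' Normalize DOIs to their canonical bare form
#'
#' Strips resolver prefixes (`https://doi.org/`, `http://dx.doi.org/`,
#' `doi:`), case-folds to lower case (the DOI system is case-insensitive) and
#' validates that the residue looks like `10.<registrant>/<suffix>`. The
#' operation is idempotent.
#'
#' @param text Character vector of DOI strings, with or without a resolver
#'   prefix.
#' @return Character vector of bare lower-case DOIs (`10.x/...`).
#' @examples
#' normalize_doi("https://doi.org/10.3897/mycokeys.83.72325")
#' @export
normalize_doi <- function(text) {
  stopifnot(is.character(text))
  if (any(is.na(text) | !nzchar(text))) {
    abort("DOI text must be non-empty", class = "taxolink_malformed_identifier")
  }
  x <- stringr::str_trim(text)
  x <- stringr::str_remove(
    x,
    stringr::regex("^(https?://(dx\\.)?doi\\.org/|doi:)", ignore_case = TRUE)
  )
  x <- tolower(x)
  bad <- !stringr::str_detect(x, "^10\\.[0-9]+(\\.[0-9]+)*/.+")
  if (any(bad)) {
    abort(
      paste0("Not a DOI: ", paste(utils::head(text[bad], 3), collapse = ", ")),
      class = "taxolink_malformed_identifier"
    )
  }
  x
}

#' Classify a raw identifier string into a persistent-identifier kind
#'
#' Heuristic classification into the kinds tracked by the package: DOI,
#' Handle, JSTOR, BioStor, BHL (Biodiversity Heritage Library), Wikidata QID,
#' PDF link or plain URL. A URL whose path ends in `.pdf` (case-insensitive)
#' is classed as a PDF link; that rule is a documented guess, since the
#' URL/PDF distinction in source databases is not formally defined.
#'
#' @param text Character vector of identifier strings.
#' @return Tibble with columns `kind` and `value` (canonicalized: bare
#'   lower-case DOIs, bare QIDs, URLs as given).
#' @export
classify_identifier <- function(text) {
  stopifnot(is.character(text))
  x <- stringr::str_trim(text)
  kind <- character(length(x))
  value <- x
  is_doi <- stringr::str_detect(
    x, stringr::regex("^(https?://(dx\\.)?doi\\.org/|doi:)?10\\.[0-9]+(\\.[0-9]+)*/.+", ignore_case = TRUE)
  )
  is_qid <- stringr::str_detect(x, "^(https?://(www\\.)?wikidata\\.org/(wiki|entity)/)?Q[0-9]+$")
  is_handle <- stringr::str_detect(x, stringr::regex("^https?://hdl\\.handle\\.net/", ignore_case = TRUE))
  is_jstor <- stringr::str_detect(x, stringr::regex("jstor\\.org", ignore_case = TRUE))
  is_biostor <- stringr::str_detect(x, stringr::regex("biostor\\.org", ignore_case = TRUE))
  is_bhl <- stringr::str_detect(x, stringr::regex("biodiversitylibrary\\.org", ignore_case = TRUE))
  is_pdf <- stringr::str_detect(x, stringr::regex("^https?://.*\\.pdf(\\?.*)?$", ignore_case = TRUE))
  is_url <- stringr::str_detect(x, stringr::regex("^https?://", ignore_case = TRUE))

  kind[is_url] <- "URL"
  kind[is_pdf] <- "PDF"
  kind[is_bhl] <- "BHL"
  kind[is_biostor] <- "BioStor"
  kind[is_jstor] <- "JSTOR"
  kind[is_handle] <- "Handle"
  kind[is_qid] <- "WikidataQID"
  kind[is_doi] <- "DOI"
  unknown <- !nzchar(kind)
  if (any(unknown)) {
    abort(
      paste0("Unrecognized identifier: ", paste(utils::head(x[unknown], 3), collapse = ", ")),
      class = "taxolink_malformed_identifier"
    )
  }
  value[kind == "DOI"] <- normalize_doi(x[kind == "DOI"])
  value[kind == "WikidataQID"] <- stringr::str_extract(x[kind == "WikidataQID"], "Q[0-9]+$")
  value[kind == "Handle"] <- stringr::str_remove(
    x[kind == "Handle"], stringr::regex("^https?://hdl\\.handle\\.net/", ignore_case = TRUE)
  )
  tibble(kind = kind, value = value)
}

#' Construct a persistent-identifier set
#'
#' Convenience constructor for the `tibble(kind, value)` shape used wherever
#' the package carries a set of persistent identifiers for a work.
#'
#' @param ... Named character scalars; names are kinds (`doi`, `qid`,
#'   `handle`, `jstor`, `biostor`, `bhl`, `url`, `pdf`). `NA` values dropped.
#' @return Tibble with columns `kind`, `value`.
#' @examples
#' pid_set(doi = "10.3897/mycokeys.83.72325", qid = "Q105740570")
#' @export
pid_set <- function(...) {
  args <- list(...)
  if (length(args) == 0) return(tibble(kind = character(), value = character()))
  key <- c(doi = "DOI", handle = "Handle", jstor = "JSTOR", biostor = "BioStor",
           bhl = "BHL", url = "URL", pdf = "PDF", qid = "WikidataQID",
           wikidataqid = "WikidataQID")
  kinds <- key[tolower(names(args))]
  if (any(is.na(kinds))) {
    abort(paste0("Unknown identifier kind: ",
                 paste(names(args)[is.na(kinds)], collapse = ", ")))
  }
  vals <- unlist(args, use.names = FALSE)
  keep <- !is.na(vals)
  out <- tibble(kind = unname(kinds[keep]), value = as.character(vals[keep]))
  out$value[out$kind == "DOI"] <- normalize_doi(out$value[out$kind == "DOI"])
  out
}

#' Default LSID authority-equivalence rules
#'
#' Some taxonomic databases mint different identifiers that share the same
#' local integer id for the same name; Index Fungorum LSIDs and MycoBank
#' records are the canonical example and can be treated as interchangeable.
#' Rules are configuration data: a tibble pairing `(authority_a, authority_b)`
#' whose identifiers with equal `object_id` are equivalent.
#'
#' @return Tibble with columns `authority_a`, `authority_b`.
#' @export
default_equivalence_rules <- function() {
  tibble(authority_a = "indexfungorum.org", authority_b = "mycobank.org")
}

#' Test whether two LSIDs identify the same name
#'
#' Two LSIDs are equivalent when they are identical, or when their authorities
#' are declared interchangeable by a rule and their local object ids are
#' equal. Unknown authorities simply compare non-equivalent.
#'
#' @param a,b LSID strings or one-row tibbles from [parse_lsid()].
#' @param rules Equivalence-rule tibble (see [default_equivalence_rules()]).
#' @return Logical vector.
#' @export
lsids_equivalent <- function(a, b, rules = default_equivalence_rules()) {
  pa <- if (is.character(a)) parse_lsid(a) else a
  pb <- if (is.character(b)) parse_lsid(b) else b
  identical_ids <- pa$authority == pb$authority &
    pa$namespace == pb$namespace &
    pa$object_id == pb$object_id
  linked <- mapply(function(x, y) {
    any((rules$authority_a == x & rules$authority_b == y) |
          (rules$authority_a == y & rules$authority_b == x))
  }, pa$authority, pb$authority, USE.NAMES = FALSE)
  identical_ids | (as.logical(linked) & pa$object_id == pb$object_id)
}

#' Pick the preferred identifier from a set
#'
#' Returns the identifier whose kind appears first in the precedence list;
#' ties within a kind are broken lexicographically on the value so the result
#' is deterministic and invariant under permutation of the input.
#'
#' @param ids Tibble with columns `kind`, `value` (see [pid_set()]).
#' @param precedence Ordered character vector of kinds;
#'   [default_precedence()] by default. Kinds absent from the list (for
#'   example `WikidataQID`) rank after all listed kinds.
#' @return One-row tibble `kind`, `value`.
#' @export
preferred_identifier <- function(ids, precedence = default_precedence()) {
  if (is.null(ids) || nrow(ids) == 0) {
    abort("Cannot pick a preferred identifier from an empty set",
          class = "taxolink_empty_set")
  }
  rank <- match(ids$kind, precedence)
  rank[is.na(rank)] <- length(precedence) + 1L
  ord <- order(rank, ids$value)
  ids[ord[1], c("kind", "value")]
}

#' Fragment identifiers for in-document pages
#'
#' A page inside a PDF or other document is addressed by suffixing the
#' work-level identifier with `#page=n`, where `n` is the 1-based position of
#' the page within the document (not the printed page number).
#'
#' @param base Character vector: a URL or resolvable identifier.
#' @param page_index Positive integer vector, 1-based page positions.
#' @return Character vector of fragment identifiers.
#' @export
fragment_identifier <- function(base, page_index) {
  page_index <- as.integer(page_index)
  if (any(is.na(page_index) | page_index < 1)) {
    abort("page_index must be a positive integer", class = "taxolink_malformed_identifier")
  }
  paste0(base, "#page=", page_index)
}

#' Parse a fragment identifier back into base and page index
#'
#' @param text Character vector produced by [fragment_identifier()].
#' @return Tibble with columns `base`, `page_index`.
#' @export
parse_fragment_identifier <- function(text) {
  m <- stringr::str_match(text, "^(.*)#page=([0-9]+)$")
  if (any(is.na(m[, 1]))) {
    abort("Not a #page=n fragment identifier", class = "taxolink_malformed_identifier")
  }
  out <- tibble(base = m[, 2], page_index = as.integer(m[, 3]))
  if (any(out$page_index < 1)) {
    abort("page_index must be >= 1", class = "taxolink_malformed_identifier")
  }
  out
}
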