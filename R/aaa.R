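#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Identifier kinds recognised throughout the package, in default precedence
# order (work-level, most citable first). Wikidata QIDs are carried alongside
# rather than competing with the work-level kinds.
PID_KINDS <- c("DOI", "Handle", "JSTOR", "BioStor", "BHL", "URL", "PDF", "WikidataQID")
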