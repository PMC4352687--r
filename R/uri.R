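# Resource URIs in the corpus come in two shapes for the same concept:
# MIRIAM URNs ("urn:miriam:obo.go:GO%3A0005892") and identifiers.org URLs
# ("http://identifiers.org/go/GO:0005892"). Both must collapse to one
# RESOURCE node.

#' Normalize an annotation resource URI to a canonical key
#'
#' Maps MIRIAM URNs and identifiers.org URLs of the same (collection,
#' accession) pair onto one canonical key, resolving percent-encoded
#' colons. Collection tags are case-folded and "obo." prefixes dropped,
#' so `urn:miriam:obo.go:GO%3A0005892` and
#' `http://identifiers.org/go/GO:0005892` agree. Unparseable text passes
#' through verbatim with a warning flag.
#'
#' @param uri Resource URI text.
#' @return List with `key` (canonical text used for deduplication),
#'   `collection`, `accession` and `parsed` (logical).
#' @export
normalize_uri <- function(uri) {
  stopifnot(is.character(uri), length(uri) == 1L, nzchar(uri))
  raw <- utils::URLdecode(uri)
  collection <- NA_character_; accession <- NA_character_
  if (grepl("^urn:miriam:", raw, ignore.case = TRUE)) {
    rest <- sub("^urn:miriam:", "", raw, ignore.case = TRUE)
    # collection is everything before the last ":" unless accession itself
    # contains one (GO:0005892); split at the first ":" after the collection
    parts <- strsplit(rest, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      collection <- parts[1]
      accession <- paste(parts[-1], collapse = ":")
    }
  } else if (grepl("^https?://(www\\.)?identifiers\\.org/", raw)) {
    rest <- sub("^https?://(www\\.)?identifiers\\.org/", "", raw)
    parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      collection <- parts[1]
      accession <- paste(parts[-1], collapse = "/")
    }
  }
  if (is.na(collection) || is.na(accession) || !nzchar(accession)) {
    return(list(key = uri, collection = NA_character_,
                accession = NA_character_, parsed = FALSE))
  }
  collection <- tolower(sub("^obo\\.", "", collection))
  # prefixed accessions ("GO:0005892") sometimes appear bare ("0005892")
  # under a prefixed collection; keep the accession as written
  list(key = paste0(collection, "/", accession),
       collection = collection, accession = accession, parsed = TRUE)
}
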