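#' Construct a document table
#'
#' A document is the unit of evaluation: one clinical note identified by a
#' `doc_id` with its full text. Character offsets in annotations refer to
#' this text, counted in Unicode code points, 0-based and half-open.
#'
#' @param doc_id Character vector of non-empty, unique document identifiers.
#' @param text Character vector of document bodies (UTF-8). Windows line
#'   endings are normalised to `"\n"` so that offsets are stable across
#'   platforms.
#' @return A tibble with columns `doc_id` and `text`, one row per document.
#' @examples
#' pii_documents("note-1", "Dr. Smith saw Ann.")
#' @export
pii_documents <- function(doc_id, text) {
  doc_id <- as.character(doc_id)
  text <- normalize_newlines(as.character(text))
  if (length(doc_id) != length(text)) {
    abort("`doc_id` and `text` must have the same length.",
          class = "piieval_usage_error")
  }
  if (any(is.na(doc_id)) || any(!nzchar(doc_id))) {
    abort("Every `doc_id` must be a non-empty string.",
          class = "piieval_usage_error")
  }
  if (anyDuplicated(doc_id)) {
    abort("`doc_id` values must be unique within a corpus.",
          class = "piieval_usage_error")
  }
  tibble(doc_id = doc_id, text = text)
}

#' Construct an annotation table
#'
#' Annotations are character-offset spans with a native category label, as
#' found in brat standoff or inline XML annotation files. Offsets are
#' 0-based, half-open `[begin, end)` and counted in Unicode code points of
#' the document text; zero-length spans are invalid. The returned table is
#' in canonical order — sorted by `(doc_id, begin, end, native_category)` —
#' which every function in the package preserves.
#'
#' @param doc_id,begin,end,native_category,provenance Vectors (recycled to a
#'   common length) giving, per span: the document it belongs to, its
#'   offsets, its category label as used by the source corpus or system, and
#'   whether it comes from the `"reference"` (gold) or the `"system"` side.
#' @return A tibble with columns `doc_id`, `begin`, `end`,
#'   `native_category`, `provenance`, canonically sorted.
#' @seealso [validate_annotations()] for checking spans against a document.
#' @examples
#' pii_annotations("note-1", c(4, 14), c(9, 17), c("Doctor", "Patient"))
#' @export
pii_annotations <- function(doc_id = character(), begin = integer(),
                            end = integer(), native_category = character(),
                            provenance = "reference") {
  out <- tibble(
    doc_id = as.character(doc_id),
    begin = as.integer(begin),
    end = as.integer(end),
    native_category = as.character(native_category),
    provenance = as.character(provenance)
  )
  bad_prov <- !out$provenance %in% c("reference", "system")
  if (any(bad_prov)) {
    abort("`provenance` must be \"reference\" or \"system\".",
          class = "piieval_usage_error")
  }
  arrange_annotations(out)
}

#' Put an annotation table in canonical order
#'
#' @param anns An annotation tibble as built by [pii_annotations()].
#' @return The same tibble sorted by `(doc_id, begin, end, native_category)`.
#' @export
arrange_annotations <- function(anns) {
  arrange(anns, .data$doc_id, .data$begin, .data$end, .data$native_category)
}

empty_annotations <- function(provenance = "system") {
  pii_annotations(provenance = provenance)
}

#' Validate annotations against their document
#'
#' Checks every span invariant: offsets in `[0, nchar(text)]`, strictly
#' positive length, non-empty category label. Validation reports problems
#' rather than failing, so a corpus audit can list every offending span.
#'
#' @param document A one-row document tibble ([pii_documents()]).
#' @param anns An annotation tibble whose `doc_id` matches `document`.
#' @return A character vector of human-readable violation descriptions, one
#'   per offending annotation; empty if all annotations are valid.
#' @examples
#' doc <- pii_documents("d1", "Dr. Smith saw Ann.")
#' validate_annotations(doc, pii_annotations("d1", 4, 9, "Doctor"))
#' validate_annotations(doc, pii_annotations("d1", 7, 7, "Date"))
#' @export
validate_annotations <- function(document, anns) {
  if (nrow(document) != 1L) {
    abort("`document` must be a single-row document table.",
          class = "piieval_usage_error")
  }
  if (nrow(anns) > 0 && !all(anns$doc_id == document$doc_id)) {
    abort(
      paste0("doc_id mismatch: annotations reference a different document ",
             "than `document` (", document$doc_id, ")."),
      class = "piieval_usage_error"
    )
  }
  len <- text_length(document$text)
  violations <- character(0)
  for (i in seq_len(nrow(anns))) {
    b <- anns$begin[i]
    e <- anns$end[i]
    where <- sprintf("annotation %d (%d, %d, %s)", i, b, e,
                     anns$native_category[i])
    if (is.na(b) || is.na(e)) {
      violations <- c(violations, paste0(where, ": missing offset"))
      next
    }
    if (b >= e) {
      violations <- c(violations,
                      paste0(where, ": zero-length or inverted span ",
                             "(begin must be < end)"))
    }
    if (b < 0) {
      violations <- c(violations, paste0(where, ": begin < 0"))
    }
    if (e > len) {
      violations <- c(violations,
                      paste0(where, ": end ", e, " > text length ", len))
    }
    if (is.na(anns$native_category[i]) || !nzchar(anns$native_category[i])) {
      violations <- c(violations, paste0(where, ": empty native_category"))
    }
  }
  violations
}

#' Validate every document of a corpus
#'
#' @param documents A document tibble.
#' @param anns An annotation tibble covering any subset of the documents.
#' @return A tibble with columns `doc_id` and `violation` (zero rows when
#'   the corpus is clean).
#' @export
validate_corpus <- function(documents, anns) {
  out <- purrr::map_dfr(seq_len(nrow(documents)), function(i) {
    doc <- documents[i, ]
    v <- validate_annotations(doc, anns[anns$doc_id == doc$doc_id, ])
    if (length(v)) tibble(doc_id = doc$doc_id, violation = v) else NULL
  })
  if (nrow(out) == 0) tibble(doc_id = character(), violation = character())
  else out
}
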