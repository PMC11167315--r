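## Readers and writers for the two supported annotation dialects and for
## score tables. Only these two input dialects are supported; converting a
## real system's native output into one of them is the caller's job.
## Text is always UTF-8 and CRLF/CR are normalised to LF before any offset
## is computed — this normalisation is part of the offset contract.

BRAT_TEXTBOUND_RE <- "^(T[0-9]+)\t([^ \t]+) ([0-9]+) ([0-9]+)(\t(.*))?$"

#' Read a brat standoff document
#'
#' Reads a `.txt` / `.ann` file pair in brat standoff format. Only
#' textbound lines (`T<id> TAB <Type> <begin> <end> TAB <surface>`) become
#' annotations; other line types (relations, events, notes, ...) are
#' ignored with a logged count. When a surface string is present it is
#' checked against the text slice the offsets select, and a mismatch is
#' warned about (offsets win).
#'
#' @param text_path Path to the document text file.
#' @param ann_path Path to the standoff annotation file.
#' @param doc_id Document identifier; defaults to the text file's base
#'   name without extension.
#' @param provenance `"reference"` or `"system"`, recorded on every
#'   annotation.
#' @return A list with elements `document` (one-row tibble, see
#'   [pii_documents()]) and `annotations` ([pii_annotations()] tibble in
#'   canonical order).
#' @export
read_brat_standoff <- function(text_path, ann_path,
                               doc_id = strip_ext(text_path),
                               provenance = "reference") {
  text <- read_text_file(text_path)
  doc <- pii_documents(doc_id, text)
  len <- text_length(doc$text)
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_textbound <- startsWith(lines, "T")
  n_other <- sum(!is_textbound)
  if (n_other > 0) {
    inform(paste0("Ignoring ", n_other, " non-textbound line(s) in ",
                  basename(ann_path), "."))
  }
  rows <- vector("list", sum(is_textbound))
  k <- 0L
  for (i in which(is_textbound)) {
    m <- regmatches(lines[[i]], regexec(BRAT_TEXTBOUND_RE, lines[[i]]))[[1]]
    if (length(m) == 0L) {
      abort(paste0("Malformed textbound line ", i, " in ",
                   basename(ann_path), ": \"", lines[[i]], "\""),
            class = "piieval_read_error")
    }
    b <- as.integer(m[[4]])
    e <- as.integer(m[[5]])
    if (b >= e || e > len) {
      abort(paste0("Offsets out of bounds on line ", i, " of ",
                   basename(ann_path), ": (", b, ", ", e,
                   ") for text of length ", len, "."),
            class = "piieval_read_error")
    }
    surface <- if (length(m) >= 7L && nzchar(m[[6]])) m[[7]] else NA_character_
    if (!is.na(surface)) {
      got <- gsub("\n", " ", substr_cp(doc$text, b, e))
      if (got != surface) {
        warn(paste0("Surface mismatch on line ", i, " of ",
                    basename(ann_path), ": file says \"", surface,
                    "\" but offsets select \"", got, "\"."))
      }
    }
    k <- k + 1L
    rows[[k]] <- tibble(doc_id = doc_id, begin = b, end = e,
                        native_category = m[[3]], provenance = provenance)
  }
  anns <- if (k > 0L) arrange_annotations(bind_rows(rows[seq_len(k)]))
          else empty_annotations(provenance)
  list(document = doc, annotations = anns)
}

#' Write a brat standoff document
#'
#' Counterpart of [read_brat_standoff()]; reading the written pair back
#' reproduces the identical annotation table.
#'
#' @param document One-row document tibble.
#' @param annotations Annotation tibble for that document.
#' @param text_path,ann_path Output paths.
#' @return Invisibly, `ann_path`.
#' @export
write_brat_standoff <- function(document, annotations, text_path, ann_path) {
  stopifnot(nrow(document) == 1L)
  write_text_file(document$text, text_path)
  annotations <- arrange_annotations(annotations)
  lines <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    surface <- gsub("\n", " ",
                    substr_cp(document$text, annotations$begin[[i]],
                              annotations$end[[i]]))
    lines[[i]] <- sprintf("T%d\t%s %d %d\t%s", i,
                          annotations$native_category[[i]],
                          annotations$begin[[i]], annotations$end[[i]],
                          surface)
  }
  con <- file(ann_path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(ann_path)
}

#' Read an inline XML document
#'
#' Reads the package's inline XML dialect, modeled on i2b2-style shared
#' task releases: a `TEXT` node holds the note body verbatim and a `TAGS`
#' node holds one empty element per annotation with `start`, `end` and
#' `TYPE` attributes (0-based, half-open offsets). A tag is kept when its
#' `TYPE` attribute (or, lacking one, its element name) equals the
#' extraction locator of some rule in `schema`; its native category is
#' that rule's name. Unmatched tags are skipped with a logged count.
#'
#' @param xml_path Path to the XML file.
#' @param schema A [pii_schema()] whose extraction locators select the
#'   tags of interest.
#' @inheritParams read_brat_standoff
#' @return A list with elements `document` and `annotations`.
#' @export
read_inline_xml <- function(xml_path, schema, doc_id = NULL,
                            provenance = "reference") {
  stopifnot(inherits(schema, "pii_schema"))
  xml <- tryCatch(
    xml2::read_xml(xml_path),
    error = function(e) {
      abort(paste0("Not well-formed XML: ", basename(xml_path), " (",
                   conditionMessage(e), ")"),
            class = "piieval_read_error")
    }
  )
  doc_id <- doc_id %||% xml2::xml_attr(xml2::xml_root(xml), "doc_id")
  if (is.na(doc_id)) doc_id <- strip_ext(xml_path)
  text_node <- xml2::xml_find_first(xml, ".//TEXT")
  if (inherits(text_node, "xml_missing")) {
    abort(paste0("No TEXT node in ", basename(xml_path), "."),
          class = "piieval_read_error")
  }
  doc <- pii_documents(doc_id, xml2::xml_text(text_node))
  len <- text_length(doc$text)
  tags_node <- xml2::xml_find_first(xml, ".//TAGS")
  tags <- if (inherits(tags_node, "xml_missing")) list()
          else xml2::xml_children(tags_node)
  rows <- list()
  n_skipped <- 0L
  for (tag in tags) {
    type <- xml2::xml_attr(tag, "TYPE")
    locator <- if (is.na(type)) xml2::xml_name(tag) else type
    hit <- match(locator, schema$rules$extract)
    if (is.na(hit)) {
      n_skipped <- n_skipped + 1L
      next
    }
    b_raw <- xml2::xml_attr(tag, "start")
    e_raw <- xml2::xml_attr(tag, "end")
    b <- suppressWarnings(as.integer(b_raw))
    e <- suppressWarnings(as.integer(e_raw))
    if (is.na(b) || is.na(e) || !grepl("^[0-9]+$", b_raw %||% "") ||
        !grepl("^[0-9]+$", e_raw %||% "")) {
      abort(paste0("Non-integer start/end on <", xml2::xml_name(tag),
                   " TYPE=\"", locator, "\"> in ", basename(xml_path), "."),
            class = "piieval_read_error")
    }
    if (b >= e || e > len) {
      abort(paste0("Offsets out of bounds on <", xml2::xml_name(tag),
                   " start=\"", b, "\" end=\"", e, "\"> in ",
                   basename(xml_path), " (text length ", len, ")."),
            class = "piieval_read_error")
    }
    rows[[length(rows) + 1L]] <- tibble(
      doc_id = doc_id, begin = b, end = e,
      native_category = schema$rules$native_name[[hit]],
      provenance = provenance
    )
  }
  if (n_skipped > 0L) {
    inform(paste0("Skipped ", n_skipped, " tag(s) in ", basename(xml_path),
                  " matching no extraction rule of schema \"",
                  schema$schema_id, "\"."))
  }
  anns <- if (length(rows)) arrange_annotations(bind_rows(rows))
          else empty_annotations(provenance)
  list(document = doc, annotations = anns)
}

#' Write an inline XML document
#'
#' Counterpart of [read_inline_xml()]. Each annotation becomes one empty
#' `<TAG start end TYPE>` element under `TAGS`; `TYPE` carries the
#' schema's extraction locator for the annotation's native category (or
#' the native category itself if no schema is given).
#'
#' @inheritParams write_brat_standoff
#' @param xml_path Output path.
#' @param schema Optional [pii_schema()] used to translate native
#'   categories to extraction locators.
#' @return Invisibly, `xml_path`.
#' @export
write_inline_xml <- function(document, annotations, xml_path,
                             schema = NULL) {
  stopifnot(nrow(document) == 1L)
  annotations <- arrange_annotations(annotations)
  locator <- annotations$native_category
  if (!is.null(schema)) {
    idx <- match(annotations$native_category, schema$rules$native_name)
    locator[!is.na(idx)] <- schema$rules$extract[idx[!is.na(idx)]]
  }
  root <- xml2::xml_new_root("document", doc_id = document$doc_id)
  text_node <- xml2::xml_add_child(root, "TEXT")
  xml2::xml_set_text(text_node, document$text)
  tags_node <- xml2::xml_add_child(root, "TAGS")
  for (i in seq_len(nrow(annotations))) {
    xml2::xml_add_child(tags_node, "TAG",
                        start = as.character(annotations$begin[[i]]),
                        end = as.character(annotations$end[[i]]),
                        TYPE = locator[[i]])
  }
  xml2::write_xml(root, xml_path)
  invisible(xml_path)
}

#' Write a score table to CSV or JSON
#'
#' The score table has the fixed header `corpus_id, system_id, tier,
#' scoring_category, policy, tp, fp, fn, precision, recall, f1, f2`.
#' Undefined metrics are serialised as an empty cell (CSV) or `null`
#' (JSON). Output is byte-identical for identical input: no timestamps,
#' locale-independent number formatting.
#'
#' @param rows A score table tibble, e.g. from [score_manifest()]; may be
#'   empty (CSV then contains only the header).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("corpus_id", "system_id", "tier", "scoring_category", "policy",
            "tp", "fp", "fn", "precision", "recall", "f1", "f2")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols)) {
    abort(paste0("Score table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "piieval_usage_error")
  }
  rows <- as_tibble(rows)[cols]
  if (format == "csv") {
    readr::write_csv(rows, path, na = "")
  } else {
    json <- jsonlite::toJSON(rows, dataframe = "rows", na = "null",
                             digits = NA, pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, useBytes = TRUE)
  }
  invisible(path)
}

## -- small file helpers ------------------------------------------------------

strip_ext <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", basename(path))
}

read_text_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "piieval_read_error")
  }
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  normalize_newlines(raw)
}

write_text_file <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(enc2utf8(text), con, eos = NULL, useBytes = TRUE)
  invisible(path)
}
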