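#' Schema configurations: native categories and tiered scoring values
#'
#' Every corpus and every deidentification system labels PII with its own
#' "native" category vocabulary (e.g. the 2006 i2b2 corpus uses `Doctor`
#' where the 2014 release uses `Doctor` under a `NAME` group and a system
#' might emit `HCPName`). A schema configuration declares, for one such
#' vocabulary, (a) how each native category is located in the annotation
#' files (the extraction locator) and (b) which shared *scoring category*
#' it maps to at each granularity tier:
#'
#' * **tier 0** — the general class of PII; every mapped category scores as
#'   `"PII"`.
#' * **tier 1** — seven high-level groups by semantic domain (`Address`,
#'   `Age`, `ContactInformation`, `Identifiers`, `Names`, `Occupations`,
#'   `Time`), plus corpus-specific paired values such as `PhoneFax`.
#' * **tier 2** — the finest-grained division, approximating the HIPAA Safe
#'   Harbor categories.
#' * **native** — no mapping; scores use the native labels themselves.
#'
#' A tier value of `"unmapped"` means the native category has no analogue
#' at that tier; such annotations are excluded from scoring entirely
#' (neither false positive nor false negative) and the exclusion is logged.
#'
#' @param schema_id Short identifier for the vocabulary (one per corpus or
#'   system).
#' @param dialect File dialect the extraction locators apply to:
#'   `"brat"` or `"inline_xml"`.
#' @param rules A data frame with columns `native_name`, `extract`, `tier0`,
#'   `tier1`, `tier2`, one row per native category.
#' @return An object of class `pii_schema`.
#' @seealso [read_schema_config()] for the on-disk format,
#'   [map_scoring_category()], [scoring_categories()].
#' @export
pii_schema <- function(schema_id, dialect = c("brat", "inline_xml"), rules) {
  dialect <- match.arg(dialect)
  rules <- as_tibble(rules)
  needed <- c("native_name", "extract", "tier0", "tier1", "tier2")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols)) {
    abort(paste0("Schema rules lack column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "piieval_config_error")
  }
  rules <- rules[needed]
  if (nrow(rules) < 1L) {
    abort("A schema needs at least one rule.", class = "piieval_config_error")
  }
  dup <- rules$native_name[duplicated(rules$native_name)]
  if (length(dup)) {
    abort(paste0("Duplicate native category name(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "piieval_config_error")
  }
  dup_ex <- rules$extract[duplicated(rules$extract)]
  if (length(dup_ex)) {
    abort(paste0("Duplicate extraction locator(s): ",
                 paste(unique(dup_ex), collapse = ", ")),
          class = "piieval_config_error")
  }
  if (any(rules$tier0 != TIER0_LABEL)) {
    abort(paste0("Every rule's tier0 score value must be \"", TIER0_LABEL,
                 "\"."),
          class = "piieval_config_error")
  }
  structure(
    list(schema_id = as.character(schema_id), dialect = dialect,
         rules = rules),
    class = "pii_schema"
  )
}

#' @export
print.pii_schema <- function(x, ...) {
  cat("<pii_schema> ", x$schema_id, " (", x$dialect, " dialect, ",
      nrow(x$rules), " native categories)\n", sep = "")
  print(x$rules, n = Inf)
  invisible(x)
}

## -- on-disk format ----------------------------------------------------------

#' Read a schema configuration file
#'
#' The file format is a sectioned key-value UTF-8 text format. A header
#' declares `schema` and `dialect`; each native category gets one
#' `[NativeName]` section with keys `extract` (the locator used when
#' reading annotation files: the brat type field, or the `TYPE` attribute /
#' element name for inline XML), and `tier0`, `tier1`, `tier2` scoring
#' values. `#` starts a comment. Example:
#'
#' ```
#' schema: i2b2-2006
#' dialect: inline_xml
#'
#' [Doctor]
#' extract: DOCTOR
#' tier0: PII
#' tier1: Names
#' tier2: Provider
#' ```
#'
#' @param path Path to a config file, or the `schema_id` of one of the
#'   configurations shipped with the package (see [shipped_schemas()]).
#' @return A validated [pii_schema()] object.
#' @export
read_schema_config <- function(path) {
  if (!file.exists(path)) {
    shipped <- shipped_schema_path(path)
    if (is.na(shipped)) {
      abort(paste0("No such schema config file or shipped schema_id: ", path),
            class = "piieval_config_error")
    }
    path <- shipped
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- list()
  rules <- list()
  current <- NULL   # name of the open section
  fields <- list()
  flush_section <- function() {
    if (is.null(current)) return()
    needed <- c("extract", "tier0", "tier1", "tier2")
    missing_keys <- setdiff(needed, names(fields))
    if (length(missing_keys)) {
      abort(paste0("Section [", current, "] in ", basename(path),
                   " is missing key(s): ",
                   paste(missing_keys, collapse = ", ")),
            class = "piieval_config_error")
    }
    rules[[length(rules) + 1L]] <<- tibble(
      native_name = current, extract = fields$extract,
      tier0 = fields$tier0, tier1 = fields$tier1, tier2 = fields$tier2
    )
  }
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      flush_section()
      current <- trimws(substr(line, 2L, nchar(line) - 1L))
      if (!nzchar(current)) {
        abort(paste0("Empty section name at line ", i, " of ",
                     basename(path)),
              class = "piieval_config_error")
      }
      fields <- list()
    } else if (grepl("^[^:]+:", line)) {
      key <- trimws(sub(":.*$", "", line))
      value <- trimws(sub("^[^:]+:", "", line))
      if (is.null(current)) header[[key]] <- value else fields[[key]] <- value
    } else {
      abort(paste0("Malformed line ", i, " of ", basename(path), ": \"",
                   lines[[i]], "\""),
            class = "piieval_config_error")
    }
  }
  flush_section()
  if (is.null(header$schema)) {
    abort(paste0("Missing `schema:` header in ", basename(path)),
          class = "piieval_config_error")
  }
  if (is.null(header$dialect)) {
    abort(paste0("Missing `dialect:` header in ", basename(path)),
          class = "piieval_config_error")
  }
  if (!length(rules)) {
    abort(paste0("No native category sections in ", basename(path)),
          class = "piieval_config_error")
  }
  pii_schema(header$schema, header$dialect, bind_rows(rules))
}

#' Write a schema configuration file
#'
#' Serialises a schema in the same sectioned key-value format that
#' [read_schema_config()] reads; reading the result back yields an
#' identical schema. Output is byte-stable for identical input.
#'
#' @param schema A [pii_schema()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_schema_config <- function(schema, path) {
  stopifnot(inherits(schema, "pii_schema"))
  lines <- c(
    paste0("schema: ", schema$schema_id),
    paste0("dialect: ", schema$dialect)
  )
  for (i in seq_len(nrow(schema$rules))) {
    r <- schema$rules[i, ]
    lines <- c(lines, "",
               paste0("[", r$native_name, "]"),
               paste0("extract: ", r$extract),
               paste0("tier0: ", r$tier0),
               paste0("tier1: ", r$tier1),
               paste0("tier2: ", r$tier2))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## -- shipped resources -------------------------------------------------------

shipped_schema_dir <- function() {
  system.file("extdata", "schemas", package = "piieval")
}

shipped_schema_path <- function(schema_id) {
  p <- file.path(shipped_schema_dir(), paste0(schema_id, ".conf"))
  if (file.exists(p)) p else NA_character_
}

#' List the schema configurations shipped with the package
#'
#' One configuration per supported corpus annotation schema (the 2006 i2b2
#' shared task, the shared 2014 i2b2/UTHealth and 2016 CEGS N-GRID schema,
#' and the MUSC corpus schema), one per deidentification system output
#' vocabulary, and `canonical` — the curated tier-2 taxonomy itself, used
#' by the synthetic generator and as the reference vocabulary of the tier
#' cross-map.
#'
#' @return A tibble with columns `schema_id` and `path`.
#' @export
shipped_schemas <- function() {
  files <- sort(list.files(shipped_schema_dir(), pattern = "\\.conf$",
                           full.names = TRUE))
  tibble(schema_id = sub("\\.conf$", "", basename(files)), path = files)
}

## -- mapping -----------------------------------------------------------------

#' Map native categories to scoring categories at a tier
#'
#' @param schema A [pii_schema()] object.
#' @param native_category Character vector of native labels.
#' @param tier One of `"native"`, `"tier0"`, `"tier1"`, `"tier2"`.
#' @return A character vector of scoring category names; `"unmapped"` for
#'   native categories the schema does not know (warned once per name per
#'   session) or that have no analogue at the requested tier.
#' @examples
#' cfg <- read_schema_config("i2b2-2006")
#' map_scoring_category(cfg, "Location", "tier1")
#' @export
map_scoring_category <- function(schema, native_category, tier = "tier2") {
  stopifnot(inherits(schema, "pii_schema"))
  tier <- check_tier(tier)
  native_category <- as.character(native_category)
  if (tier == "native") return(native_category)
  idx <- match(native_category, schema$rules$native_name)
  unknown <- unique(native_category[is.na(idx)])
  if (length(unknown)) {
    warn_once(
      paste0(schema$schema_id, "\r", unknown),
      function(k) {
        nm <- sub("^[^\r]*\r", "", k)
        paste0("Native category \"", nm, "\" has no rule in schema \"",
               schema$schema_id, "\"; scoring it as \"", UNMAPPED, "\".")
      }
    )
  }
  out <- rep(UNMAPPED, length(native_category))
  hit <- !is.na(idx)
  out[hit] <- schema$rules[[tier]][idx[hit]]
  out
}

#' List the scoring categories a schema produces at a tier
#'
#' @inheritParams map_scoring_category
#' @return Character vector of distinct scoring category names at that
#'   tier, lexicographically sorted, excluding `"unmapped"`.
#' @examples
#' scoring_categories(read_schema_config("canonical"), "tier1")
#' @export
scoring_categories <- function(schema, tier = "tier2") {
  stopifnot(inherits(schema, "pii_schema"))
  tier <- check_tier(tier)
  vals <- if (tier == "native") schema$rules$native_name
          else schema$rules[[tier]]
  sort(setdiff(unique(vals), UNMAPPED))
}
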