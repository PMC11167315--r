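## Batch evaluation: a run manifest names corpora (documents + reference
## annotations + schema) and systems (output dirs per corpus + schema),
## and scoring loops over corpus x system x tier x policy, emitting one
## score-table row per cell. The score table is a pure function of the
## manifest and the files it points to: no clocks, no locale, no ordering
## dependence.

#' Read and validate a run manifest
#'
#' The manifest is a YAML file:
#'
#' ```yaml
#' output_dir: scores
#' tiers: [tier0, tier1]
#' policies: [exact, partial, fully_contained]
#' collapsed: true
#' corpora:
#'   synth:
#'     dialect: brat            # or inline_xml
#'     documents: corpus/txt    # .txt files (brat only)
#'     reference: corpus/ref    # .ann or .xml files
#'     schema: canonical        # shipped schema_id or a file path
#' systems:
#'   degraded:
#'     dialect: brat
#'     schema: canonical
#'     outputs:
#'       synth: corpus/sys
#' ```
#'
#' Relative paths are resolved against the manifest's directory. String
#' values may interpolate environment variables as `${VAR}`, honouring
#' pipeline conventions built on environment-variable configuration.
#'
#' @param path Path to the manifest file.
#' @return A validated `pii_manifest` object (schemas already loaded).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such manifest: ", path), class = "piieval_usage_error")
  }
  base <- dirname(normalizePath(path))
  m <- yaml::read_yaml(path)
  m <- interpolate_env(m)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  tiers <- unlist(m$tiers) %||% character(0)
  policies <- unlist(m$policies) %||% character(0)
  if (!length(m$corpora) || !length(m$systems) || !length(tiers) ||
      !length(policies)) {
    abort(paste0("Manifest needs at least one corpus, one system, one ",
                 "tier and one policy."),
          class = "piieval_usage_error")
  }
  for (t in tiers) check_tier(t)
  for (p in policies) check_policy(p)
  load_schema <- function(s) {
    resolved <- resolve(s)
    if (!is.null(resolved) && file.exists(resolved)) {
      read_schema_config(resolved)
    } else {
      read_schema_config(s)  # shipped schema_id or absolute path
    }
  }
  corpora <- imap(m$corpora, function(cc, id) {
    dialect <- cc$dialect %||% "brat"
    ref <- resolve(cc$reference)
    docs <- resolve(cc$documents)
    if (is.null(ref) || !dir.exists(ref)) {
      abort(paste0("Corpus \"", id, "\": reference dir not found: ",
                   cc$reference %||% "<missing>"),
            class = "piieval_usage_error")
    }
    if (dialect == "brat" && (is.null(docs) || !dir.exists(docs))) {
      abort(paste0("Corpus \"", id, "\": documents dir not found: ",
                   cc$documents %||% "<missing>"),
            class = "piieval_usage_error")
    }
    list(corpus_id = id, dialect = dialect, documents = docs,
         reference = ref, schema = load_schema(cc$schema))
  })
  systems <- imap(m$systems, function(ss, id) {
    list(system_id = id, dialect = ss$dialect %||% "brat",
         schema = load_schema(ss$schema),
         outputs = map(ss$outputs, resolve),
         command = ss$command)
  })
  structure(
    list(
      output_dir = resolve(m$output_dir %||% "scores"),
      tiers = tiers, policies = policies,
      collapsed = isTRUE(m$collapsed %||% TRUE),
      corpora = corpora, systems = systems
    ),
    class = "pii_manifest"
  )
}

interpolate_env <- function(x) {
  if (is.list(x)) return(lapply(x, interpolate_env))
  if (is.character(x)) {
    for (i in seq_along(x)) {
      while (grepl("\\$\\{[^}]+\\}", x[[i]])) {
        var <- sub(".*\\$\\{([^}]+)\\}.*", "\\1", x[[i]])
        x[[i]] <- sub(paste0("\\$\\{", var, "\\}"), Sys.getenv(var),
                      x[[i]])
      }
    }
  }
  x
}

## Read all documents + annotations of one side of a corpus from disk.
read_annotation_dir <- function(dialect, documents_dir, ann_dir, schema,
                                provenance, expected_docs = NULL) {
  anns <- list()
  docs <- list()
  missing <- character(0)
  if (dialect == "brat") {
    txts <- sort(list.files(documents_dir, pattern = "\\.txt$",
                            full.names = TRUE))
    for (txt in txts) {
      stem <- strip_ext(txt)
      ann_path <- file.path(ann_dir, paste0(stem, ".ann"))
      if (!file.exists(ann_path)) {
        missing <- c(missing, stem)
        next
      }
      r <- read_brat_standoff(txt, ann_path, doc_id = stem,
                              provenance = provenance)
      docs[[stem]] <- r$document
      anns[[stem]] <- r$annotations
    }
  } else {
    xmls <- sort(list.files(ann_dir, pattern = "\\.xml$",
                            full.names = TRUE))
    for (x in xmls) {
      r <- read_inline_xml(x, schema, provenance = provenance)
      docs[[r$document$doc_id]] <- r$document
      anns[[r$document$doc_id]] <- r$annotations
    }
    if (!is.null(expected_docs)) {
      missing <- setdiff(expected_docs, names(docs))
    }
  }
  list(
    documents = if (length(docs)) bind_rows(docs) else
      tibble(doc_id = character(), text = character()),
    annotations = if (length(anns)) {
      arrange_annotations(bind_rows(anns))
    } else {
      empty_annotations(provenance)
    },
    missing = missing
  )
}

#' Score every corpus x system x tier x policy cell of a manifest
#'
#' The batch evaluation loop: for each corpus, the reference annotations
#' are read once; each system's outputs for that corpus are read and
#' scored at every requested tier under every requested policy. At tier 0
#' only the collapsed `"ALL"` row is emitted (per-category and collapsed
#' coincide there); at other tiers one row per scoring category in the
#' union of the two schemas' vocabularies (zero-count categories
#' included, so the table shape depends only on the manifest), plus an
#' `"ALL"` row when the manifest asks for collapsed evaluation. A system
#' output directory that is missing produces an error record rather than
#' silent absence.
#'
#' Results are written to `<output_dir>/scores.csv` and `scores.json`
#' (see [write_score_table()]), a structured run log of
#' unmapped-annotation and missing-document counts to `run.log`, and any
#' error records to `errors.csv`.
#'
#' @param manifest A `pii_manifest` from [read_manifest()].
#' @return Invisibly, a `pii_run` object: list with `scores` (tibble),
#'   `errors` (tibble), `log` (character), and `status` (0 ok, 2 if any
#'   error records).
#' @export
score_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "pii_manifest"))
  rows <- list()
  errors <- list()
  log_lines <- character(0)
  for (corpus in manifest$corpora) {
    ref <- read_annotation_dir(corpus$dialect, corpus$documents,
                               corpus$reference, corpus$schema,
                               provenance = "reference")
    if (length(ref$missing)) {
      log_lines <- c(log_lines, sprintf(
        "corpus %s: %d document(s) without reference annotations",
        corpus$corpus_id, length(ref$missing)))
    }
    for (system in manifest$systems) {
      out_dir <- system$outputs[[corpus$corpus_id]]
      if (is.null(out_dir) || !dir.exists(out_dir)) {
        errors[[length(errors) + 1L]] <- tibble(
          corpus_id = corpus$corpus_id, system_id = system$system_id,
          error = paste0("system output directory missing: ",
                         out_dir %||% "<not declared>"))
        next
      }
      sys <- read_annotation_dir(system$dialect, corpus$documents,
                                 out_dir, system$schema,
                                 provenance = "system",
                                 expected_docs = ref$documents$doc_id)
      if (length(sys$missing)) {
        log_lines <- c(log_lines, sprintf(
          "corpus %s / system %s: %d document(s) without system output (scored as all-miss)",
          corpus$corpus_id, system$system_id, length(sys$missing)))
      }
      for (tier in manifest$tiers) {
        for (policy in manifest$policies) {
          ev <- evaluate_corpus(ref$annotations, sys$annotations,
                                corpus$schema, system$schema,
                                tier = tier, policy = policy)
          if (sum(ev$n_unmapped) > 0) {
            log_lines <- c(log_lines, sprintf(
              "corpus %s / system %s / %s / %s: %d reference + %d system annotation(s) unmapped (excluded)",
              corpus$corpus_id, system$system_id, tier, policy,
              ev$n_unmapped[["reference"]], ev$n_unmapped[["system"]]))
          }
          cell_rows <- list()
          if (tier != "tier0") {
            cats <- sort(union(scoring_categories(corpus$schema, tier),
                               scoring_categories(system$schema, tier)))
            per_cat <- left_join(tibble(category = cats), ev$counts,
                                 by = "category")
            per_cat[is.na(per_cat$tp), c("tp", "fp", "fn")] <- 0L
            cell_rows$per_cat <- per_cat
          }
          if (tier == "tier0" || manifest$collapsed) {
            cell_rows$all <- ev$collapsed
          }
          cell <- add_metrics(bind_rows(cell_rows))
          rows[[length(rows) + 1L]] <- mutate(
            rename(cell, scoring_category = "category"),
            corpus_id = corpus$corpus_id, system_id = system$system_id,
            tier = tier, policy = policy, .before = 1L)
        }
      }
    }
  }
  scores <- if (length(rows)) bind_rows(rows) else score_table_skeleton()
  errors <- if (length(errors)) bind_rows(errors) else
    tibble(corpus_id = character(), system_id = character(),
           error = character())
  dir.create(manifest$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_score_table(scores, file.path(manifest$output_dir, "scores.csv"),
                    "csv")
  write_score_table(scores, file.path(manifest$output_dir, "scores.json"),
                    "json")
  writeLines(log_lines, file.path(manifest$output_dir, "run.log"))
  if (nrow(errors)) {
    readr::write_csv(errors, file.path(manifest$output_dir, "errors.csv"))
  }
  out <- structure(
    list(scores = structure(scores,
                            class = c("pii_scores", class(scores))),
         errors = errors, log = log_lines,
         status = if (nrow(errors)) 2L else 0L),
    class = "pii_run"
  )
  invisible(out)
}

score_table_skeleton <- function() {
  tibble(
    corpus_id = character(), system_id = character(), tier = character(),
    scoring_category = character(), policy = character(),
    tp = integer(), fp = integer(), fn = integer(),
    precision = double(), recall = double(), f1 = double(), f2 = double()
  )
}

#' @export
print.pii_run <- function(x, ...) {
  cat("<pii_run> ", nrow(x$scores), " score rows, ", nrow(x$errors),
      " error(s), status ", x$status, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus and degraded system output to disk
#'
#' Generates a reference corpus, degrades it through the error channel,
#' and writes both sides in both supported dialects, together with a
#' `params.yaml` record and a ready-to-run `manifest.yaml`, so reader
#' tests and pipeline tests share the same fixtures:
#'
#' ```
#' out_dir/brat/txt/*.txt   out_dir/brat/ref/*.ann   out_dir/brat/sys/*.ann
#' out_dir/xml/ref/*.xml    out_dir/xml/sys/*.xml
#' out_dir/params.yaml      out_dir/manifest.yaml
#' ```
#'
#' @param gen A [generator_params()] object.
#' @param pert A [perturbation_params()] object.
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the in-memory `corpus`, the degraded
#'   `system_annotations`, and `dir`.
#' @export
simulate_corpus <- function(gen, pert, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    abort(paste0("Output directory not empty: ", out_dir,
                 " (use overwrite = TRUE to replace)."),
          class = "piieval_usage_error")
  }
  corpus <- generate_reference_corpus(gen)
  sys_anns <- perturb_to_system_output(corpus, pert)
  schema <- read_schema_config("canonical")
  for (d in c("brat/txt", "brat/ref", "brat/sys", "xml/ref", "xml/sys")) {
    dir.create(file.path(out_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (i in seq_len(nrow(corpus$documents))) {
    doc <- corpus$documents[i, ]
    ref <- corpus$annotations[corpus$annotations$doc_id == doc$doc_id, ]
    sys <- sys_anns[sys_anns$doc_id == doc$doc_id, ]
    write_brat_standoff(doc, ref,
                        file.path(out_dir, "brat/txt",
                                  paste0(doc$doc_id, ".txt")),
                        file.path(out_dir, "brat/ref",
                                  paste0(doc$doc_id, ".ann")))
    write_brat_standoff(doc, sys,
                        file.path(out_dir, "brat/txt",
                                  paste0(doc$doc_id, ".txt")),
                        file.path(out_dir, "brat/sys",
                                  paste0(doc$doc_id, ".ann")))
    write_inline_xml(doc, ref,
                     file.path(out_dir, "xml/ref",
                               paste0(doc$doc_id, ".xml")), schema)
    write_inline_xml(doc, sys,
                     file.path(out_dir, "xml/sys",
                               paste0(doc$doc_id, ".xml")), schema)
  }
  yaml::write_yaml(
    list(
      generator = unclass(gen)[setdiff(names(gen), "filler_alphabet")],
      generator_filler_alphabet = paste(gen$filler_alphabet,
                                        collapse = ""),
      perturbation = unclass(pert)
    ),
    file.path(out_dir, "params.yaml")
  )
  yaml::write_yaml(
    list(
      output_dir = "scores",
      tiers = list("tier0", "tier1", "tier2"),
      policies = list("exact", "partial", "fully_contained"),
      collapsed = TRUE,
      corpora = list(synthetic = list(
        dialect = "brat", documents = "brat/txt", reference = "brat/ref",
        schema = "canonical")),
      systems = list(degraded = list(
        dialect = "brat", schema = "canonical",
        outputs = list(synthetic = "brat/sys")))
    ),
    file.path(out_dir, "manifest.yaml")
  )
  invisible(list(corpus = corpus, system_annotations = sys_anns,
                 dir = out_dir))
}

#' Run an external deidentification command over a corpus, with timing
#'
#' Substitutes each note's path into `command_template` (placeholders
#' `{input}` and `{output}`), runs the commands through the shell, and
#' reports wall-clock throughput as both seconds per note (lower is
#' better) and notes per second (higher is better). The command's output
#' is not parsed — scoring is a separate step over the files it writes.
#' Timing excludes nothing the commands do (start-up cost per note is
#' included) and is inherently hardware-dependent, so these numbers are
#' descriptive, never asserted against.
#'
#' @param command_template Shell command with `{input}` and `{output}`
#'   placeholders, both required.
#' @param documents_dir Directory of note files (each becomes `{input}`).
#' @param output_dir Directory for per-note outputs (`{output}` is the
#'   note's basename inside it).
#' @param corpus_id,system_id Labels recorded on the timing row.
#' @return A one-row timing tibble: `corpus_id`, `system_id`, `n_notes`,
#'   `elapsed_seconds`, `seconds_per_note`, `notes_per_second`,
#'   `n_failed`, `complete`. Failed notes (nonzero exit) are listed in
#'   the `failures` attribute and flag the record incomplete.
#' @export
run_external <- function(command_template, documents_dir, output_dir,
                         corpus_id = "corpus", system_id = "system") {
  if (!grepl("{input}", command_template, fixed = TRUE) ||
      !grepl("{output}", command_template, fixed = TRUE)) {
    abort("`command_template` must contain {input} and {output}.",
          class = "piieval_usage_error")
  }
  notes <- sort(list.files(documents_dir, full.names = TRUE))
  notes <- notes[!dir.exists(notes)]
  if (!length(notes)) {
    abort(paste0("No note files in ", documents_dir, "."),
          class = "piieval_usage_error")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- character(0)
  t0 <- Sys.time()
  for (note in notes) {
    cmd <- gsub("{input}", shQuote(note), command_template, fixed = TRUE)
    cmd <- gsub("{output}",
                shQuote(file.path(output_dir, basename(note))), cmd,
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) failures <- c(failures, note)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out <- tibble(
    corpus_id = corpus_id, system_id = system_id,
    n_notes = length(notes), elapsed_seconds = elapsed,
    seconds_per_note = elapsed / length(notes),
    notes_per_second = length(notes) / elapsed,
    n_failed = length(failures), complete = length(failures) == 0L
  )
  attr(out, "failures") <- failures
  out
}
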