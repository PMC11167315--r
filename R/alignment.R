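#' Span matching predicates
#'
#' The three alignment semantics deciding whether a reference span and a
#' system span count as a match:
#'
#' * `"exact"` — the character offsets of the two annotations must be the
#'   same.
#' * `"partial"` — any part of the two annotations overlaps.
#' * `"fully_contained"` — the system annotation covers the entirety of
#'   the reference annotation; it may include more text before or after
#'   the reference extent but not less. This predicate is asymmetric: for
#'   deidentification it certifies that no PII leaks outside the redacted
#'   region, which a mere partial overlap cannot.
#'
#' The three predicates nest: every exact match is fully contained, and
#' every containing pair overlaps.
#'
#' @param ref_begin,ref_end Reference span offsets (0-based, half-open).
#' @param sys_begin,sys_end System span offsets. All four vectors are
#'   recycled to a common length.
#' @param policy One of `"exact"`, `"partial"`, `"fully_contained"`.
#' @return A logical vector.
#' @examples
#' spans_match(5, 10, 8, 15, "partial")          # TRUE
#' spans_match(5, 10, 8, 15, "fully_contained")  # FALSE: starts too late
#' spans_match(5, 10, 3, 12, "fully_contained")  # TRUE
#' @export
spans_match <- function(ref_begin, ref_end, sys_begin, sys_end, policy) {
  policy <- check_policy(policy)
  if (any(ref_begin >= ref_end) || any(sys_begin >= sys_end)) {
    abort("Invalid span: begin must be < end.",
          class = "piieval_usage_error")
  }
  switch(policy,
    exact = ref_begin == sys_begin & ref_end == sys_end,
    partial = pmax(ref_begin, sys_begin) < pmin(ref_end, sys_end),
    fully_contained = sys_begin <= ref_begin & sys_end >= ref_end
  )
}

## Maximum-cardinality one-to-one bipartite matching by augmenting paths
## (Kuhn's algorithm). `adj` is a list over reference spans, each element
## the preference-ordered integer candidates on the system side. Reference
## spans are processed in canonical (begin) order and candidates in
## preference order, so among equal-cardinality matchings the result
## deterministically prefers earlier reference begins and larger overlaps.
## Returns, per system span, the index of its matched reference (NA if
## unmatched).
kuhn_match <- function(adj, n_sys) {
  sys_match <- rep(NA_integer_, n_sys)
  visited <- logical(n_sys)
  try_augment <- function(i) {
    for (j in adj[[i]]) {
      if (!visited[[j]]) {
        visited[[j]] <<- TRUE
        if (is.na(sys_match[[j]]) || try_augment(sys_match[[j]])) {
          sys_match[[j]] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (i in seq_along(adj)) {
    visited[] <- FALSE
    try_augment(i)
  }
  sys_match
}

## Match one reference table against one system table under a policy;
## both tables carry begin/end and are in canonical order. Returns a
## two-column tibble of (ref_idx, sys_idx) matched index pairs.
match_spans_one_to_one <- function(ref, sys, policy) {
  nr <- nrow(ref)
  ns <- nrow(sys)
  if (nr == 0L || ns == 0L) {
    return(tibble(ref_idx = integer(), sys_idx = integer()))
  }
  adj <- vector("list", nr)
  for (i in seq_len(nr)) {
    ok <- which(spans_match(ref$begin[[i]], ref$end[[i]],
                            sys$begin, sys$end, policy))
    if (length(ok) > 1L) {
      overlap <- pmin(ref$end[[i]], sys$end[ok]) -
        pmax(ref$begin[[i]], sys$begin[ok])
      ok <- ok[order(-overlap, sys$begin[ok], sys$end[ok])]
    }
    adj[[i]] <- ok
  }
  sys_match <- kuhn_match(adj, ns)
  j <- which(!is.na(sys_match))
  out <- tibble(ref_idx = sys_match[j], sys_idx = j)
  arrange(out, .data$ref_idx)
}

map_and_split <- function(anns, schema, tier) {
  category <- map_scoring_category(schema, anns$native_category, tier)
  keep <- category != UNMAPPED
  list(
    anns = mutate(anns[keep, ], category = category[keep]),
    n_unmapped = sum(!keep)
  )
}

pair_rows <- function(ref, sys, idx, category) {
  if (nrow(idx) == 0L) {
    return(tibble(
      category = character(), ref_begin = integer(), ref_end = integer(),
      ref_native = character(), sys_begin = integer(), sys_end = integer(),
      sys_native = character()
    ))
  }
  tibble(
    category = category,
    ref_begin = ref$begin[idx$ref_idx], ref_end = ref$end[idx$ref_idx],
    ref_native = ref$native_category[idx$ref_idx],
    sys_begin = sys$begin[idx$sys_idx], sys_end = sys$end[idx$sys_idx],
    sys_native = sys$native_category[idx$sys_idx]
  )
}

#' Score one document: align reference and system annotations
#'
#' Implements the per-note evaluation: both annotation sets are mapped to
#' scoring categories at the requested tier (annotations whose category is
#' `"unmapped"` at that tier are excluded from scoring and counted), a
#' bipartite graph of span pairs satisfying the matching policy is built,
#' and a maximum-cardinality one-to-one matching selects the true
#' positives. Unmatched reference spans are false negatives; unmatched
#' system spans are false positives.
#'
#' Two tallies are produced in one pass:
#'
#' * **per category** — pairs must agree on scoring category; a reference
#'   of category A overlapped only by a system span of category B yields
#'   `fn(A)` and `fp(B)`, so confusions surface as paired fn/fp, never as
#'   a true positive.
#' * **collapsed** — category labels are ignored and any policy-satisfying
#'   span pair may match; all tallies go to the single category `"ALL"`.
#'
#' One-to-one matching makes the conservation laws hold in every cell:
#' `tp + fn` equals the number of (mapped) reference annotations and
#' `tp + fp` the number of (mapped) system annotations.
#'
#' @param ref,sys Annotation tibbles ([pii_annotations()]) for a single
#'   shared document; `sys` may be empty.
#' @param ref_schema,sys_schema Schema configurations ([pii_schema()]) for
#'   the reference and system vocabularies; `sys_schema` defaults to
#'   `ref_schema`.
#' @param tier Granularity tier at which categories are compared.
#' @param policy Span matching policy, see [spans_match()].
#' @param doc_id Document id; inferred from the annotations when `NULL`.
#' @return A `pii_doc_eval` object: a list with the per-category counts
#'   tibble (`counts`), the collapsed one-row tibble (`collapsed`), the
#'   matched-pair tables (`pairs`, `collapsed_pairs`), and unmapped-span
#'   tallies. Use [tidy()] / [glance()] to get metric tables.
#' @examples
#' cfg <- read_schema_config("canonical")
#' ref <- pii_annotations("d", c(0, 6), c(5, 10), "Patient")
#' sys <- pii_annotations("d", 4, 8, "Patient", provenance = "system")
#' glance(evaluate_document(ref, sys, cfg, policy = "partial"))
#' @export
evaluate_document <- function(ref, sys, ref_schema, sys_schema = ref_schema,
                              tier = "tier2", policy = "partial",
                              doc_id = NULL) {
  tier <- check_tier(tier)
  policy <- check_policy(policy)
  ids <- unique(c(ref$doc_id, sys$doc_id))
  if (length(ids) > 1L) {
    abort(paste0("doc_id mismatch: annotations span documents ",
                 paste(ids, collapse = ", ")),
          class = "piieval_usage_error")
  }
  doc_id <- doc_id %||% (if (length(ids)) ids else NA_character_)

  ref_m <- map_and_split(arrange_annotations(ref), ref_schema, tier)
  sys_m <- map_and_split(arrange_annotations(sys), sys_schema, tier)
  refs <- ref_m$anns
  syss <- sys_m$anns

  # per-category matching
  cats <- sort(unique(c(refs$category, syss$category)))
  per_cat <- vector("list", length(cats))
  pair_list <- vector("list", length(cats))
  for (k in seq_along(cats)) {
    cat_k <- cats[[k]]
    r <- refs[refs$category == cat_k, ]
    s <- syss[syss$category == cat_k, ]
    idx <- match_spans_one_to_one(r, s, policy)
    per_cat[[k]] <- tibble(
      category = cat_k,
      tp = nrow(idx),
      fp = nrow(s) - nrow(idx),
      fn = nrow(r) - nrow(idx)
    )
    pair_list[[k]] <- pair_rows(r, s, idx, cat_k)
  }
  counts <- if (length(per_cat)) bind_rows(per_cat) else {
    tibble(category = character(), tp = integer(), fp = integer(),
           fn = integer())
  }

  # collapsed matching: labels ignored
  idx_all <- match_spans_one_to_one(refs, syss, policy)
  collapsed <- tibble(
    category = COLLAPSED_LABEL,
    tp = nrow(idx_all),
    fp = nrow(syss) - nrow(idx_all),
    fn = nrow(refs) - nrow(idx_all)
  )

  structure(
    list(
      doc_id = doc_id, tier = tier, policy = policy,
      counts = counts, collapsed = collapsed,
      pairs = bind_rows(pair_list),
      collapsed_pairs = pair_rows(refs, syss, idx_all, COLLAPSED_LABEL),
      n_unmapped = c(reference = ref_m$n_unmapped, system = sys_m$n_unmapped)
    ),
    class = "pii_doc_eval"
  )
}

#' @export
print.pii_doc_eval <- function(x, ...) {
  cat("<pii_doc_eval> doc ", x$doc_id, " [", x$tier, ", ", x$policy, "]\n",
      sep = "")
  print(add_metrics(bind_rows(x$counts, x$collapsed)))
  invisible(x)
}

#' Score a corpus: micro-aggregate document evaluations
#'
#' Documents are the matching universe — annotations never match across
#' documents — so corpus-level counts are the element-wise sum of
#' per-document counts. A document present on the reference side but
#' missing from the system side contributes all its reference annotations
#' as false negatives (it is scored against an empty system set).
#'
#' @param ref,sys Annotation tibbles covering any number of documents;
#'   rows are paired per `doc_id`.
#' @inheritParams evaluate_document
#' @return A `pii_corpus_eval` object with summed per-category counts
#'   (`counts`), collapsed counts (`collapsed`), per-document counts
#'   (`by_doc`), and bookkeeping tallies. [tidy()] returns the
#'   per-category table with precision/recall/F1/F2; [glance()] the
#'   collapsed one-row summary.
#' @export
evaluate_corpus <- function(ref, sys, ref_schema, sys_schema = ref_schema,
                            tier = "tier2", policy = "partial") {
  tier <- check_tier(tier)
  policy <- check_policy(policy)
  doc_ids <- sort(unique(c(ref$doc_id, sys$doc_id)))
  missing_sys <- setdiff(unique(ref$doc_id), unique(sys$doc_id))
  evals <- map(doc_ids, function(d) {
    evaluate_document(
      ref[ref$doc_id == d, ], sys[sys$doc_id == d, ],
      ref_schema, sys_schema, tier = tier, policy = policy, doc_id = d
    )
  })
  by_doc <- bind_rows(map(evals, function(e) {
    mutate(bind_rows(e$counts, e$collapsed), doc_id = e$doc_id,
           .before = 1L)
  }))
  sum_counts <- function(df) {
    if (nrow(df) == 0L) {
      return(tibble(category = character(), tp = integer(), fp = integer(),
                    fn = integer()))
    }
    summarise(group_by(df, .data$category),
              tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              .groups = "drop")
  }
  counts_all <- sum_counts(bind_rows(map(evals, "counts")))
  collapsed <- sum_counts(bind_rows(map(evals, "collapsed")))
  if (nrow(collapsed) == 0L) {
    collapsed <- tibble(category = COLLAPSED_LABEL, tp = 0L, fp = 0L,
                        fn = 0L)
  }
  n_unmapped <- Reduce(`+`, map(evals, "n_unmapped"),
                       c(reference = 0L, system = 0L))
  structure(
    list(
      tier = tier, policy = policy,
      counts = arrange(counts_all, .data$category),
      collapsed = collapsed,
      by_doc = by_doc,
      n_docs = length(doc_ids),
      n_missing_system_docs = length(missing_sys),
      n_unmapped = n_unmapped
    ),
    class = "pii_corpus_eval"
  )
}

#' @export
print.pii_corpus_eval <- function(x, ...) {
  cat("<pii_corpus_eval> ", x$n_docs, " documents [", x$tier, ", ",
      x$policy, "]\n", sep = "")
  print(add_metrics(bind_rows(x$counts, x$collapsed)))
  if (x$n_missing_system_docs > 0) {
    cat("note:", x$n_missing_system_docs,
        "document(s) had no system output (scored as all-miss)\n")
  }
  if (sum(x$n_unmapped) > 0) {
    cat("note:", x$n_unmapped[["reference"]], "reference and",
        x$n_unmapped[["system"]],
        "system annotation(s) unmapped at this tier (excluded)\n")
  }
  invisible(x)
}
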