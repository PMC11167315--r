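## Synthetic corpus generator: stands in for the restricted shared-task
## corpora. Documents are random filler text with planted, mutually
## non-overlapping PII spans labelled from the canonical tier-2 taxonomy;
## a parameterised error channel degrades the reference into a "system
## output" with known miss / spurious / jitter / confusion rates, so the
## whole scoring pipeline can be checked against closed-form expectations.

## The curated fine-grained (tier 2) taxonomy, grouped by the seven tier-1
## semantic domains. Kept in sync with inst/extdata/schemas/canonical.conf
## (a unit test enforces the correspondence).
CANONICAL_TIER2 <- list(
  Names = c("Patient", "Provider", "Relative", "OtherPerson"),
  Address = c("Street", "City", "State", "Country", "Zip", "Hospital",
              "Organization", "OtherGeo"),
  Age = "Age",
  ContactInformation = c("Phone", "Fax", "Email", "URL", "IPAddress"),
  Identifiers = c("SSN", "MedicalRecord", "HealthPlan", "Account",
                  "License", "Vehicle", "Device", "BioID", "OtherID"),
  Occupations = "Occupation",
  Time = "Date"
)

#' Default per-category sampling weights for planted PII
#'
#' Relative frequencies loosely shaped like PII in real clinical notes —
#' dates and provider names dominate, patient names and institution
#' names are common, exotic identifier types are rare. Every category of
#' the canonical tier-2 taxonomy gets positive weight so fine-grained
#' cells are exercised.
#'
#' @return A named numeric vector over the canonical tier-2 categories.
#' @export
default_category_weights <- function() {
  w <- c(
    Date = 20, Provider = 15, Patient = 8, Hospital = 6, MedicalRecord = 5,
    Age = 4, Phone = 3, Street = 2, City = 2, Relative = 1, OtherPerson = 1,
    Organization = 1, State = 1, Zip = 1, OtherGeo = 1, Email = 1, Fax = 1,
    Occupation = 1
  )
  rest <- setdiff(unlist(CANONICAL_TIER2, use.names = FALSE), names(w))
  c(w, setNames(rep(0.5, length(rest)), rest))
}

#' Parameters for the synthetic reference corpus generator
#'
#' @param n_docs Number of documents.
#' @param mean_annotations_per_doc Poisson mean of planted PII spans per
#'   document.
#' @param category_weights Named nonnegative sampling weights over tier-2
#'   categories; at least one must be positive.
#' @param mean_span_length Mean planted span length in characters
#'   (lengths are `1 + Poisson(mean_span_length - 1)`).
#' @param mean_gap_length Mean filler-gap length between consecutive
#'   planted spans (gaps are `2 + Poisson(mean_gap_length - 2)`, so spans
#'   never touch).
#' @param filler_alphabet Character vector of symbols used for the
#'   non-PII filler text.
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters.
#' @return A validated `pii_generator_params` list.
#' @export
generator_params <- function(n_docs = 250,
                             mean_annotations_per_doc = 20,
                             category_weights = default_category_weights(),
                             mean_span_length = 8,
                             mean_gap_length = 20,
                             filler_alphabet = c(letters, " "),
                             seed = 1L) {
  if (n_docs < 0 || n_docs != floor(n_docs)) {
    abort("`n_docs` must be a nonnegative integer.",
          class = "piieval_usage_error")
  }
  if (mean_annotations_per_doc <= 0) {
    abort("`mean_annotations_per_doc` must be positive.",
          class = "piieval_usage_error")
  }
  if (mean_span_length < 1) {
    abort("`mean_span_length` must be >= 1.", class = "piieval_usage_error")
  }
  if (mean_gap_length < 2) {
    abort("`mean_gap_length` must be >= 2.", class = "piieval_usage_error")
  }
  if (is.null(names(category_weights)) || any(category_weights < 0) ||
      !any(category_weights > 0)) {
    abort(paste0("`category_weights` must be a named vector of nonnegative ",
                 "weights with at least one positive entry."),
          class = "piieval_usage_error")
  }
  if (!length(filler_alphabet) || any(nchar(filler_alphabet) != 1L)) {
    abort("`filler_alphabet` must be single characters.",
          class = "piieval_usage_error")
  }
  structure(
    list(n_docs = as.integer(n_docs),
         mean_annotations_per_doc = mean_annotations_per_doc,
         category_weights = category_weights,
         mean_span_length = mean_span_length,
         mean_gap_length = mean_gap_length,
         filler_alphabet = filler_alphabet,
         seed = as.integer(seed)),
    class = "pii_generator_params"
  )
}

#' Parameters of the error channel degrading reference into system output
#'
#' @param p_miss Probability that a reference annotation is dropped
#'   entirely (a false negative).
#' @param spurious_rate Poisson mean of extra system spans per document,
#'   placed inside filler regions only — a spurious span never overlaps a
#'   planted one, so each is a guaranteed false positive.
#' @param jitter_mode `"none"`, `"expand_only"` (boundaries may move
#'   outward only, so the jittered span still fully contains its
#'   reference), or `"shift"` (either boundary may move either way).
#' @param jitter_max Maximum displacement per boundary, in characters.
#'   Spans pushed past the document edge are clipped, never an error.
#' @param confusion Optional named list: for a true tier-2 category, a
#'   named probability vector over emitted categories (rows must sum to
#'   1). Categories without an entry are emitted unchanged.
#' @param seed Integer seed for the channel's randomness.
#' @return A validated `pii_perturbation_params` list.
#' @export
perturbation_params <- function(p_miss = 0.2,
                                spurious_rate = 2,
                                jitter_mode = c("none", "expand_only",
                                                "shift"),
                                jitter_max = 2L,
                                confusion = NULL,
                                seed = 2L) {
  jitter_mode <- match.arg(jitter_mode)
  if (p_miss < 0 || p_miss > 1) {
    abort("`p_miss` must lie in [0, 1].", class = "piieval_usage_error")
  }
  if (spurious_rate < 0) {
    abort("`spurious_rate` must be nonnegative.",
          class = "piieval_usage_error")
  }
  if (jitter_max < 0 || jitter_max != floor(jitter_max)) {
    abort("`jitter_max` must be a nonnegative integer.",
          class = "piieval_usage_error")
  }
  if (!is.null(confusion)) {
    if (is.null(names(confusion))) {
      abort("`confusion` must be a named list of probability vectors.",
            class = "piieval_usage_error")
    }
    for (nm in names(confusion)) {
      row <- confusion[[nm]]
      if (is.null(names(row)) || any(row < 0) ||
          abs(sum(row) - 1) > 1e-8) {
        abort(paste0("Confusion row for \"", nm,
                     "\" must be named probabilities summing to 1."),
              class = "piieval_usage_error")
      }
    }
  }
  structure(
    list(p_miss = p_miss, spurious_rate = spurious_rate,
         jitter_mode = jitter_mode, jitter_max = as.integer(jitter_max),
         confusion = confusion, seed = as.integer(seed)),
    class = "pii_perturbation_params"
  )
}

random_chars <- function(n, alphabet) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference corpus
#'
#' Each document is built by interleaving random filler gaps with planted
#' PII spans, so planted spans are mutually non-overlapping, separated by
#' at least two filler characters, and in-bounds by construction. Span
#' content is drawn from an uppercase alphabet (the scoring engine is
#' offset-based and never inspects content, so textual realism buys
#' nothing). The output is a deterministic function of the parameters,
#' including the seed.
#'
#' @param params A [generator_params()] object.
#' @return A `pii_corpus`: list with `documents` (tibble) and
#'   `annotations` (reference-provenance tibble), plus the params.
#' @export
generate_reference_corpus <- function(params) {
  stopifnot(inherits(params, "pii_generator_params"))
  w <- params$category_weights
  w <- w[w > 0]
  with_seed(params$seed, {
    docs <- vector("list", params$n_docs)
    anns <- vector("list", params$n_docs)
    for (d in seq_len(params$n_docs)) {
      doc_id <- sprintf("doc%05d", d)
      k <- rpois(1L, params$mean_annotations_per_doc)
      span_len <- 1L + rpois(k, params$mean_span_length - 1)
      gap_len <- 2L + rpois(k + 1L, params$mean_gap_length - 2)
      pieces <- character(2L * k + 1L)
      begins <- integer(k)
      pos <- 0L
      for (i in seq_len(k)) {
        pieces[[2L * i - 1L]] <- random_chars(gap_len[[i]],
                                              params$filler_alphabet)
        pos <- pos + gap_len[[i]]
        begins[[i]] <- pos
        pieces[[2L * i]] <- random_chars(span_len[[i]], LETTERS)
        pos <- pos + span_len[[i]]
      }
      pieces[[2L * k + 1L]] <- random_chars(gap_len[[k + 1L]],
                                            params$filler_alphabet)
      docs[[d]] <- tibble(doc_id = doc_id,
                          text = paste(pieces, collapse = ""))
      if (k > 0L) {
        anns[[d]] <- tibble(
          doc_id = doc_id, begin = begins,
          end = begins + span_len,
          native_category = sample(names(w), k, replace = TRUE, prob = w),
          provenance = "reference"
        )
      }
    }
    documents <- if (params$n_docs > 0L) bind_rows(docs) else
      tibble(doc_id = character(), text = character())
    annotations <- if (length(anns) && any(!vapply(anns, is.null, TRUE))) {
      arrange_annotations(bind_rows(anns))
    } else {
      empty_annotations("reference")
    }
    structure(
      list(documents = documents, annotations = annotations,
           params = params),
      class = "pii_corpus"
    )
  })
}

#' @export
print.pii_corpus <- function(x, ...) {
  cat("<pii_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$annotations), " planted annotations\n", sep = "")
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Degrade a reference corpus into a synthetic system output
#'
#' Applies the error channel document by document: each reference span is
#' independently dropped with probability `p_miss`; survivors have their
#' boundaries jittered per `jitter_mode` (clipped to the document) and
#' their category relabelled per the `confusion` rows; finally
#' `Poisson(spurious_rate)` spurious spans per document are placed inside
#' filler gaps, never overlapping any planted span. Deterministic given
#' the channel seed.
#'
#' The four error phases draw from independent RNG substreams derived
#' from the channel seed (miss, spurious, jitter, confusion in that
#' order), so switching one phase on or off never perturbs the draws of
#' another: the same seed drops the same spans and plants the same
#' spurious spans whether or not jitter is enabled.
#'
#' @param corpus A `pii_corpus` from [generate_reference_corpus()].
#' @param params A [perturbation_params()] object.
#' @return An annotation tibble with provenance `"system"`.
#' @export
perturb_to_system_output <- function(corpus, params) {
  stopifnot(inherits(corpus, "pii_corpus"),
            inherits(params, "pii_perturbation_params"))
  weights <- corpus$params$category_weights
  weights <- weights[weights > 0]
  mean_len <- corpus$params$mean_span_length
  anns <- corpus$annotations
  doc_len <- setNames(text_length(corpus$documents$text),
                      corpus$documents$doc_id)

  # phase 1 (seed): independent misses across the whole corpus
  surv <- with_seed(params$seed, {
    anns[runif(nrow(anns)) >= params$p_miss, ]
  })

  # phase 2 (seed + 1): spurious spans inside filler gaps, per document;
  # depends only on the reference layout, never on the other phases
  spur <- with_seed(params$seed + 1L, {
    out <- list()
    for (d in corpus$documents$doc_id) {
      m <- rpois(1L, params$spurious_rate)
      if (m == 0L) next
      gaps <- filler_gaps(anns[anns$doc_id == d, ], doc_len[[d]])
      if (nrow(gaps) == 0L) next
      gl <- gaps$end - gaps$begin
      for (j in seq_len(m)) {
        g <- sample.int(nrow(gaps), 1L, prob = gl)
        size <- min(1L + rpois(1L, mean_len - 1), gl[[g]])
        start <- gaps$begin[[g]] + sample.int(gl[[g]] - size + 1L, 1L) - 1L
        out[[length(out) + 1L]] <- tibble(
          doc_id = d, begin = start, end = start + size,
          native_category = sample(names(weights), 1L, prob = weights),
          provenance = "system"
        )
      }
    }
    if (length(out)) bind_rows(out) else NULL
  })

  # phase 3 (seed + 2): boundary jitter on the survivors
  ns <- nrow(surv)
  if (ns > 0L && params$jitter_mode != "none" && params$jitter_max > 0L) {
    jmax <- params$jitter_max
    len <- unname(doc_len[surv$doc_id])
    surv <- with_seed(params$seed + 2L, {
      if (params$jitter_mode == "expand_only") {
        surv$begin <- clip(surv$begin -
                             (sample.int(jmax + 1L, ns, TRUE) - 1L),
                           0L, len)
        surv$end <- clip(surv$end +
                           (sample.int(jmax + 1L, ns, TRUE) - 1L),
                         0L, len)
      } else {
        db <- sample.int(2L * jmax + 1L, ns, TRUE) - jmax - 1L
        de <- sample.int(2L * jmax + 1L, ns, TRUE) - jmax - 1L
        surv$begin <- clip(surv$begin + db, 0L, len - 1L)
        surv$end <- clip(surv$end + de, surv$begin + 1L, len)
      }
      surv
    })
  }

  # phase 4 (seed + 3): category confusion on the survivors
  if (ns > 0L && !is.null(params$confusion)) {
    surv <- with_seed(params$seed + 3L, {
      for (i in seq_len(ns)) {
        row <- params$confusion[[surv$native_category[[i]]]]
        if (!is.null(row)) {
          surv$native_category[[i]] <- sample(names(row), 1L, prob = row)
        }
      }
      surv
    })
  }

  surv$provenance <- rep("system", ns)
  res <- bind_rows(surv, spur)
  if (nrow(res) == 0L) empty_annotations("system")
  else arrange_annotations(res)
}

## Maximal sub-intervals of [0, len) not covered by any reference span.
filler_gaps <- function(refs, len) {
  if (nrow(refs) == 0L) return(tibble(begin = 0L, end = as.integer(len)))
  refs <- arrange(refs, .data$begin)
  starts <- c(0L, refs$end)
  ends <- c(refs$begin, as.integer(len))
  keep <- starts < ends
  tibble(begin = starts[keep], end = ends[keep])
}

#' Closed-form expected metrics of the error channel
#'
#' With no jitter or expand-only jitter, a surviving system span always
#' still matches its reference under the `partial` and `fully_contained`
#' policies (expansion only adds text around the reference extent), and a
#' spurious span never matches anything (it lives in filler). Collapsed
#' tier-0 metrics then have closed-form expectations:
#' \deqn{E[recall] = 1 - p_{miss}}
#' \deqn{E[precision] = \frac{N (1-p_{miss})}{N (1-p_{miss}) + D s}}
#' with `N = n_docs * mean_annotations_per_doc` planted spans, `D =
#' n_docs` and `s = spurious_rate`. These are expectations over the
#' channel, not per-seed values. No closed form is claimed for shift
#' jitter or the exact policy, which the function rejects.
#'
#' @param gen A [generator_params()] object.
#' @param pert A [perturbation_params()] object with `jitter_mode` in
#'   `{"none", "expand_only"}`.
#' @param policy `"partial"` or `"fully_contained"`.
#' @return A one-row tibble with columns `policy`, `precision`, `recall`.
#' @export
expected_metrics <- function(gen, pert, policy = "partial") {
  stopifnot(inherits(gen, "pii_generator_params"),
            inherits(pert, "pii_perturbation_params"))
  policy <- check_policy(policy)
  if (policy == "exact") {
    abort("No closed form for the exact policy.",
          class = "piieval_unsupported_error")
  }
  if (pert$jitter_mode == "shift") {
    abort("No closed form for shift jitter.",
          class = "piieval_unsupported_error")
  }
  n_planted <- gen$n_docs * gen$mean_annotations_per_doc
  surviving <- n_planted * (1 - pert$p_miss)
  spurious <- gen$n_docs * pert$spurious_rate
  tibble(
    policy = policy,
    precision = if (surviving + spurious > 0) {
      surviving / (surviving + spurious)
    } else NA_real_,
    recall = 1 - pert$p_miss
  )
}
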