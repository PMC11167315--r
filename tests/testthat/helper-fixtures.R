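# Shared fixtures: tiny schemas, random annotation sides, and an
# independent brute-force matching oracle used to check the alignment
# engine. The oracle re-derives the span predicates from first principles
# (plain interval arithmetic) and enumerates every one-to-one matching,
# so it shares no code with the implementation it audits.

toy_schema <- function(categories = c("A", "B"), group = "G",
                       dialect = "brat") {
  pii_schema(
    "toy", dialect,
    tibble::tibble(
      native_name = categories, extract = categories,
      tier0 = "PII", tier1 = group, tier2 = categories
    )
  )
}

ref_side <- function(begin, end, cat = "A", doc = "d") {
  pii_annotations(doc, begin, end, cat, provenance = "reference")
}

sys_side <- function(begin, end, cat = "A", doc = "d") {
  pii_annotations(doc, begin, end, cat, provenance = "system")
}

# A random annotation side: up to n_max spans with lengths 1..4 inside a
# document of doc_len code points; overlapping and nested spans allowed.
random_side <- function(n_max = 6, doc_len = 30, cats = c("A", "B"),
                        provenance = "reference", doc = "d") {
  n <- sample(0:n_max, 1)
  if (n == 0) {
    return(pii_annotations(provenance = provenance))
  }
  b <- sample(0:(doc_len - 2L), n, replace = TRUE)
  e <- pmin(doc_len, b + sample(1:4, n, replace = TRUE))
  pii_annotations(doc, b, e, sample(cats, n, replace = TRUE),
                  provenance = provenance)
}

# First-principles span predicates (independent of spans_match()).
oracle_pair_ok <- function(rb, re, sb, se, policy) {
  switch(policy,
    exact = rb == sb && re == se,
    partial = max(rb, sb) < min(re, se),
    fully_contained = sb <= rb && se >= re
  )
}

# Maximum one-to-one matching cardinality by exhaustive search over all
# assignments of reference spans to distinct admissible system spans.
oracle_max_matching <- function(ref, sys, policy, by_category = TRUE) {
  nr <- nrow(ref)
  ns <- nrow(sys)
  if (nr == 0 || ns == 0) return(0L)
  ok <- matrix(FALSE, nr, ns)
  for (i in seq_len(nr)) {
    for (j in seq_len(ns)) {
      ok[i, j] <- oracle_pair_ok(ref$begin[i], ref$end[i],
                                 sys$begin[j], sys$end[j], policy) &&
        (!by_category ||
           ref$native_category[i] == sys$native_category[j])
    }
  }
  best <- 0L
  recurse <- function(i, used, size) {
    if (size + (nr - i + 1L) <= best) return()  # cannot beat best
    if (i > nr) {
      if (size > best) best <<- size
      return()
    }
    recurse(i + 1L, used, size)  # leave ref i unmatched
    for (j in seq_len(ns)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, size + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(ns), 0L)
  best
}

# Per-category oracle: sum of per-category maximum matchings.
oracle_per_category_tp <- function(ref, sys, policy) {
  cats <- union(ref$native_category, sys$native_category)
  sum(vapply(cats, function(cc) {
    oracle_max_matching(ref[ref$native_category == cc, ],
                        sys[sys$native_category == cc, ],
                        policy, by_category = FALSE)
  }, integer(1)))
}
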