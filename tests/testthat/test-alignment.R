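test_that("span predicates follow their definitions", {
  for (p in c("exact", "partial", "fully_contained")) {
    expect_true(spans_match(5, 10, 5, 10, p))
  }
  expect_true(spans_match(5, 10, 8, 15, "partial"))
  expect_false(spans_match(5, 10, 8, 15, "fully_contained"))
  expect_true(spans_match(5, 10, 3, 12, "fully_contained"))
  expect_false(spans_match(3, 12, 5, 10, "fully_contained"))  # asymmetric
  expect_false(spans_match(0, 5, 5, 9, "partial"))  # touching, no overlap
  expect_error(spans_match(5, 5, 0, 3, "exact"),
               class = "piieval_usage_error")
})

test_that("a system span can satisfy only one reference (one-to-one)", {
  sch <- toy_schema("N")
  ev <- evaluate_document(
    ref_side(c(0, 6), c(5, 10), "N"), sys_side(4, 8, "N"),
    sch, policy = "partial"
  )
  expect_equal(ev$collapsed[, c("tp", "fp", "fn")],
               tibble::tibble(tp = 1L, fp = 0L, fn = 1L))
  ev2 <- evaluate_document(
    ref_side(0, 10, "N"), sys_side(c(0, 5), c(4, 10), "N"),
    sch, policy = "partial"
  )
  expect_equal(ev2$counts$tp, 1L)
  expect_equal(ev2$counts$fp, 1L)
  expect_equal(ev2$counts$fn, 0L)
})

test_that("category equality is required per category but not collapsed", {
  sch <- pii_schema("names", "brat", tibble::tibble(
    native_name = c("Patient", "Provider"),
    extract = c("Patient", "Provider"),
    tier0 = "PII", tier1 = "Names", tier2 = c("Patient", "Provider")
  ))
  ev <- evaluate_document(
    ref_side(0, 5, "Patient"), sys_side(0, 5, "Provider"),
    sch, tier = "tier2", policy = "exact"
  )
  expect_equal(sum(ev$counts$tp), 0L)
  expect_equal(sum(ev$counts$fn), 1L)
  expect_equal(sum(ev$counts$fp), 1L)
  # confusion shows up as paired fn/fp in the right categories
  expect_equal(ev$counts$fn[ev$counts$category == "Patient"], 1L)
  expect_equal(ev$counts$fp[ev$counts$category == "Provider"], 1L)
  # collapsed matching ignores the labels; so does tier0 mapping
  expect_equal(ev$collapsed$tp, 1L)
  ev0 <- evaluate_document(
    ref_side(0, 5, "Patient"), sys_side(0, 5, "Provider"),
    sch, tier = "tier0", policy = "exact"
  )
  expect_equal(ev0$counts$tp, 1L)
})

test_that("annotations from different documents refuse to mix", {
  sch <- toy_schema()
  expect_error(
    evaluate_document(ref_side(0, 5, doc = "d1"),
                      sys_side(0, 5, doc = "d2"), sch),
    class = "piieval_usage_error"
  )
})

test_that("unmapped categories are excluded from scoring entirely", {
  sch <- pii_schema("x", "brat", tibble::tibble(
    native_name = c("A", "Junk"), extract = c("A", "Junk"),
    tier0 = "PII", tier1 = c("G", "unmapped"), tier2 = c("A", "unmapped")
  ))
  ev <- evaluate_document(
    ref_side(c(0, 10), c(5, 15), c("A", "Junk")),
    sys_side(c(0, 10), c(5, 15), c("A", "Junk")),
    sch, tier = "tier2", policy = "exact"
  )
  expect_equal(ev$counts$category, "A")
  expect_equal(ev$collapsed$tp, 1L)  # only the mapped pair counts
  expect_equal(unname(ev$n_unmapped), c(1L, 1L))
})

test_that("matched pairs are reported in reference order with offsets", {
  sch <- toy_schema("N")
  ev <- evaluate_document(
    ref_side(c(0, 10), c(5, 14), "N"),
    sys_side(c(9, 1), c(15, 4), "N"),
    sch, policy = "partial"
  )
  expect_equal(ev$pairs$ref_begin, c(0L, 10L))
  expect_equal(ev$pairs$sys_begin, c(1L, 9L))
})

test_that("engine tp equals exhaustive-enumeration tp on random documents", {
  set.seed(421)
  sch <- toy_schema(c("A", "B"))
  for (rep in 1:120) {
    ref <- random_side(5, provenance = "reference")
    sys <- random_side(5, provenance = "system")
    for (policy in c("exact", "partial", "fully_contained")) {
      ev <- evaluate_document(ref, sys, sch, tier = "tier2",
                              policy = policy)
      expect_equal(sum(ev$counts$tp),
                   oracle_per_category_tp(ref, sys, policy))
      expect_equal(ev$collapsed$tp,
                   oracle_max_matching(ref, sys, policy,
                                       by_category = FALSE))
    }
  }
})

test_that("matching agrees with an independent graph-library matcher", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (rep in 1:60) {
    ref <- random_side(6)
    sys <- random_side(6, provenance = "system")
    for (policy in c("partial", "fully_contained")) {
      ev <- evaluate_document(ref, sys, toy_schema(c("A", "B")),
                              policy = policy)
      nr <- nrow(ref)
      ns <- nrow(sys)
      expected <- 0
      if (nr > 0 && ns > 0) {
        ok <- outer(seq_len(nr), seq_len(ns), function(i, j) {
          spans_match(ref$begin[i], ref$end[i], sys$begin[j], sys$end[j],
                      policy)
        })
        edges <- which(ok, arr.ind = TRUE)
        if (nrow(edges)) {
          g <- igraph::make_bipartite_graph(
            types = c(rep(FALSE, nr), rep(TRUE, ns)),
            edges = as.vector(t(cbind(edges[, 1], nr + edges[, 2])))
          )
          expected <- igraph::max_bipartite_match(g)$matching_size
        }
      }
      expect_equal(ev$collapsed$tp, expected)
    }
  }
})

test_that("conservation and collapse dominance hold on random inputs", {
  set.seed(7)
  sch <- toy_schema(c("A", "B", "C"))
  for (rep in 1:200) {
    ref <- random_side(6, cats = c("A", "B", "C"))
    sys <- random_side(6, cats = c("A", "B", "C"), provenance = "system")
    policy <- sample(c("exact", "partial", "fully_contained"), 1)
    ev <- evaluate_document(ref, sys, sch, policy = policy)
    expect_equal(sum(ev$counts$tp) + sum(ev$counts$fn), nrow(ref))
    expect_equal(sum(ev$counts$tp) + sum(ev$counts$fp), nrow(sys))
    for (k in seq_len(nrow(ev$counts))) {
      cc <- ev$counts$category[k]
      expect_equal(ev$counts$tp[k] + ev$counts$fn[k],
                   sum(ref$native_category == cc))
      expect_equal(ev$counts$tp[k] + ev$counts$fp[k],
                   sum(sys$native_category == cc))
    }
    expect_gte(ev$collapsed$tp, sum(ev$counts$tp))
    expect_equal(ev$collapsed$tp + ev$collapsed$fn, nrow(ref))
    expect_equal(ev$collapsed$tp + ev$collapsed$fp, nrow(sys))
  }
})

test_that("policies nest: tp(exact) <= tp(fully_contained) <= tp(partial)", {
  set.seed(11)
  sch <- toy_schema(c("A", "B"))
  for (rep in 1:150) {
    ref <- random_side(6)
    sys <- random_side(6, provenance = "system")
    tps <- vapply(c("exact", "fully_contained", "partial"), function(p) {
      evaluate_document(ref, sys, sch, policy = p)$collapsed$tp
    }, integer(1))
    expect_true(tps[["exact"]] <= tps[["fully_contained"]])
    expect_true(tps[["fully_contained"]] <= tps[["partial"]])
  }
})

test_that("partial matching is ref/sys symmetric; containment is not", {
  set.seed(13)
  sch <- toy_schema(c("A", "B"))
  broke_symmetry <- FALSE
  for (rep in 1:80) {
    ref <- random_side(5)
    sys <- random_side(5, provenance = "system")
    fwd <- evaluate_document(ref, sys, sch, policy = "partial")
    ref2 <- dplyr::mutate(sys, provenance = "reference")
    sys2 <- dplyr::mutate(ref, provenance = "system")
    bwd <- evaluate_document(ref2, sys2, sch, policy = "partial")
    expect_equal(fwd$collapsed$tp, bwd$collapsed$tp)
    f1 <- evaluate_document(ref, sys, sch, policy = "fully_contained")
    b1 <- evaluate_document(ref2, sys2, sch, policy = "fully_contained")
    if (f1$collapsed$tp != b1$collapsed$tp) broke_symmetry <- TRUE
  }
  expect_true(broke_symmetry)
})

test_that("corpus evaluation sums documents and handles missing system docs", {
  sch <- toy_schema("N")
  ref <- dplyr::bind_rows(
    ref_side(0, 5, "N", doc = "a"),
    ref_side(c(0, 6, 12, 18), c(5, 10, 16, 22), "N", doc = "b")
  )
  sys <- sys_side(0, 5, "N", doc = "a")  # doc b missing entirely
  ev <- evaluate_corpus(ref, sys, sch, policy = "exact")
  expect_equal(ev$collapsed$tp, 1L)
  expect_equal(ev$collapsed$fn, 4L)
  expect_equal(ev$collapsed$fp, 0L)
  expect_equal(ev$n_missing_system_docs, 1L)

  empty <- evaluate_corpus(pii_annotations(), pii_annotations(), sch)
  expect_equal(nrow(empty$counts), 0L)
  expect_equal(empty$collapsed[, c("tp", "fp", "fn")],
               tibble::tibble(tp = 0L, fp = 0L, fn = 0L))
})

test_that("tidy and glance expose metric tables", {
  sch <- toy_schema("N")
  ev <- evaluate_corpus(ref_side(c(0, 6), c(5, 10), "N"),
                        sys_side(0, 5, "N"), sch, policy = "exact")
  td <- tidy(ev)
  expect_equal(td$precision, 1)
  expect_equal(td$recall, 0.5)
  gl <- glance(ev)
  expect_equal(gl$category, "ALL")
  expect_equal(gl$f1, 2 / 3, tolerance = 1e-9)
})
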