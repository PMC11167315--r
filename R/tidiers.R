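#' Tidy evaluation results into metric tables
#'
#' `tidy()` returns one row per scoring category with counts and
#' precision/recall/F1/F2 (undefined metrics are `NA`); `glance()` returns
#' the one-row collapsed ("ALL") summary in which category labels were
#' ignored during matching.
#'
#' @param x A `pii_doc_eval` or `pii_corpus_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @name pii_tidiers
NULL

#' @rdname pii_tidiers
#' @method tidy pii_doc_eval
#' @export
tidy.pii_doc_eval <- function(x, ...) {
  mutate(add_metrics(x$counts), tier = x$tier, policy = x$policy,
         .before = 1L)
}

#' @rdname pii_tidiers
#' @method tidy pii_corpus_eval
#' @export
tidy.pii_corpus_eval <- function(x, ...) {
  mutate(add_metrics(x$counts), tier = x$tier, policy = x$policy,
         .before = 1L)
}

#' @rdname pii_tidiers
#' @method glance pii_doc_eval
#' @export
glance.pii_doc_eval <- function(x, ...) {
  out <- add_metrics(x$collapsed)
  mutate(out, tier = x$tier, policy = x$policy, .before = 1L)
}

#' @rdname pii_tidiers
#' @method glance pii_corpus_eval
#' @export
glance.pii_corpus_eval <- function(x, ...) {
  out <- add_metrics(x$collapsed)
  mutate(out, tier = x$tier, policy = x$policy, .before = 1L)
}
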