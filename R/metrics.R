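#' Precision, recall and F-beta from TP/FP/FN counts
#'
#' Binary span-detection metrics computed from a count triple: `precision
#' = tp / (tp + fp)`, `recall = tp / (tp + fn)` (recall is also called
#' sensitivity), and the F-beta score
#' \deqn{F_\beta = (1+\beta^2) \, P R / (\beta^2 P + R).}
#' `beta = 1` gives the harmonic mean of precision and recall; `beta = 2`
#' weights recall above precision, apt for deidentification where missed
#' PII is costlier than over-redaction.
#'
#' A zero denominator yields `NA` — the *undefined* sentinel — never an
#' imputed 0 or 1: a system that emits nothing has no meaningful
#' precision, and the distinction must stay visible downstream (undefined
#' cells are skipped, and counted, by [macro_average()]).
#'
#' @param tp,fp,fn Nonnegative integer vectors (recycled) of true
#'   positive, false positive and false negative counts.
#' @param beta Positive scalar weight on recall.
#' @return A numeric vector in `[0, 1]`, with `NA` where undefined.
#' @examples
#' precision(tp = 3, fp = 1)   # 0.75
#' recall(tp = 3, fn = 2)      # 0.6
#' f_beta(3, 1, 2)             # 0.6667: harmonic mean of 0.75 and 0.6
#' f_beta(3, 1, 2, beta = 2)   # 0.625: recall-weighted
#' @export
precision <- function(tp, fp) {
  check_counts(tp, fp)
  denom <- tp + fp
  ifelse(denom > 0, tp / denom, NA_real_)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  check_counts(tp, fn)
  denom <- tp + fn
  ifelse(denom > 0, tp / denom, NA_real_)
}

#' @rdname precision
#' @export
f_beta <- function(tp, fp, fn, beta = 1) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.",
          class = "piieval_usage_error")
  }
  p <- precision(tp, fp)
  r <- recall(tp, fn)
  f_beta_pr(p, r, beta)
}

## F-beta from precision and recall vectors; NA if either side is
## undefined or both are zero.
f_beta_pr <- function(p, r, beta = 1) {
  b2 <- beta^2
  out <- ifelse(
    is.na(p) | is.na(r) | (p == 0 & r == 0),
    NA_real_,
    (1 + b2) * p * r / (b2 * p + r)
  )
  out
}

check_counts <- function(...) {
  for (x in list(...)) {
    if (!is.numeric(x) || any(!is.na(x) & (x < 0 | x != floor(x)))) {
      abort("Counts must be nonnegative integers.",
            class = "piieval_usage_error")
    }
  }
  invisible(NULL)
}

#' Macro-average a set of metric values
#'
#' The unweighted mean of the *defined* values — e.g. per-corpus recall
#' averaged across corpora. Undefined (`NA`) inputs are skipped, and the
#' number skipped is reported alongside so silent exclusion is impossible;
#' if every input is undefined the macro average is itself undefined.
#' Contrast with the micro average, which is obtained by summing count
#' triples before computing the metric.
#'
#' @param values Numeric vector of metric values, `NA` for undefined.
#' @return A one-row tibble with columns `value`, `n_used`, `n_skipped`.
#' @examples
#' macro_average(c(0.5, NA, 1.0))
#' @export
macro_average <- function(values) {
  values <- as.numeric(values)
  defined <- values[!is.na(values)]
  tibble(
    value = if (length(defined)) mean(defined) else NA_real_,
    n_used = length(defined),
    n_skipped = sum(is.na(values))
  )
}

## Append precision/recall/f1/f2 columns to a tp/fp/fn counts table.
add_metrics <- function(counts) {
  mutate(
    counts,
    precision = precision(.data$tp, .data$fp),
    recall = recall(.data$tp, .data$fn),
    f1 = f_beta(.data$tp, .data$fp, .data$fn, beta = 1),
    f2 = f_beta(.data$tp, .data$fp, .data$fn, beta = 2)
  )
}
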