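## Shared internal helpers: controlled vocabularies, seeded evaluation,
## newline normalisation and deduplicated unmapped-category warnings.

PII_TIERS <- c("native", "tier0", "tier1", "tier2")
PII_POLICIES <- c("exact", "partial", "fully_contained")
TIER0_LABEL <- "PII"
UNMAPPED <- "unmapped"
COLLAPSED_LABEL <- "ALL"

check_tier <- function(tier) {
  if (!is.character(tier) || length(tier) != 1L || !tier %in% PII_TIERS) {
    abort(paste0("`tier` must be one of: ", paste(PII_TIERS, collapse = ", ")),
          class = "piieval_usage_error")
  }
  tier
}

check_policy <- function(policy) {
  if (!is.character(policy) || length(policy) != 1L ||
      !policy %in% PII_POLICIES) {
    abort(paste0("`policy` must be one of: ",
                 paste(PII_POLICIES, collapse = ", ")),
          class = "piieval_usage_error")
  }
  policy
}

## Run `expr` under a fixed RNG seed, restoring any pre-existing RNG state.
## All randomness in the package flows through this helper so that no
## function perturbs (or depends on) the caller's global random state.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## CRLF (and lone CR) are normalised to LF before any offsets are computed;
## this normalisation is part of the package's offset contract.
normalize_newlines <- function(x) {
  gsub("\r\n?", "\n", x)
}

## Count in Unicode code points, not bytes.
text_length <- function(x) {
  stringr::str_length(x)
}

substr_cp <- function(x, begin, end) {
  # 0-based half-open [begin, end) in code points
  stringr::str_sub(x, begin + 1L, end)
}

## -- deduplicated warnings ---------------------------------------------------

the <- new.env(parent = emptyenv())
the$warned <- character(0)

#' Reset the memo of already-issued unmapped-category warnings
#'
#' Unknown native categories trigger a warning once per (schema, name) pair
#' per session; call this to re-arm all warnings (used mainly in tests).
#'
#' @return Invisibly, `NULL`.
#' @export
reset_unmapped_warnings <- function() {
  the$warned <- character(0)
  invisible(NULL)
}

warn_once <- function(keys, message_fun) {
  new <- setdiff(unique(keys), the$warned)
  if (length(new)) {
    the$warned <- c(the$warned, new)
    for (k in new) warn(message_fun(k), class = "piieval_unmapped_warning")
  }
  invisible(NULL)
}
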