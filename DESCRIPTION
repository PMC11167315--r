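Package: piieval
Title: Schema-Mapped Span Alignment Scoring for Clinical Text
    Deidentification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An extensible scoring engine for evaluating clinical text
    deidentification (PII/PHI tagging) systems against reference
    annotations. Annotations are character-offset spans read from brat
    standoff or inline XML files; declarative schema configurations map
    each corpus's or system's native categories onto shared scoring
    categories at three granularity tiers; reference and system spans are
    aligned per document by maximum one-to-one matching under exact,
    partial, or fully-contained span semantics; and true/false
    positive/negative counts are turned into precision, recall, and
    F-beta scores with micro and macro aggregation. A synthetic corpus
    generator with a parameterised error channel (misses, spurious spans,
    boundary jitter, category confusion) provides fixtures with
    closed-form expected metrics in place of restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
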