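# piieval

A scoring engine for evaluating clinical text **deidentification**
systems. Deidentification tools tag spans of personally identifiable
information (PII) — names, dates, addresses, identifiers — in clinical
notes; `piieval` measures how well a system's spans agree with
human-curated reference annotations, even when the two sides use
incompatible category vocabularies.

It is aimed at clinical NLP researchers and the staff scientists who
have to vet a deidentification tool before deployment: people who need
one reproducible pipeline that scores any system against any annotated
corpus with the same alignment rules and the same category cross-map,
instead of one-off comparisons that cannot be placed side by side.

## What it computes

Annotations are character-offset spans, 0-based and half-open, counted
in Unicode code points. Per document, reference and system spans are
aligned by a **maximum one-to-one bipartite matching** over pairs that
satisfy a span-matching policy:

- **exact** — identical offsets;
- **partial** — any overlap;
- **fully contained** — the system span covers the entire reference
  span (may extend beyond it, never short of it) — the privacy-relevant
  criterion, since it certifies no PII leaks outside the redaction.

Matched pairs are true positives; unmatched reference spans are false
negatives; unmatched system spans are false positives. From the counts:

```
P = tp / (tp + fp)      R = tp / (tp + fn)
F_beta = (1 + beta^2) P R / (beta^2 P + R)
```

with `F1` the harmonic mean and `F2` recall-weighted (missed PII is
costlier than over-redaction). Undefined cells (0/0) stay `NA` rather
than being imputed, and macro averages report how many such cells they
skipped.

Category vocabularies are bridged by declarative **schema
configurations** mapping each native category to shared scoring
categories at three tiers: tier 0 (everything is `PII`), tier 1 (seven
semantic groups: Address, Age, ContactInformation, Identifiers, Names,
Occupations, Time), tier 2 (fine-grained, HIPAA-style). Configurations
for the standard deidentification shared-task corpus schemas and for six
off-the-shelf system vocabularies ship with the package
(`shipped_schemas()`).

Because the standard corpora are restricted, the package also contains a
**synthetic corpus generator** with a parameterised error channel
(misses, spurious spans, boundary jitter, category confusion) whose
collapsed precision and recall have closed-form expectations — the basis
of the package's end-to-end tests.

## Worked example

A handcrafted synthetic note ships with the package. Its "system output"
misses the patient's age, widens the patient-name span, and mislabels
the provider as a patient:

```r
library(piieval)

sample_dir <- system.file("extdata", "sample-synthetic", package = "piieval")
ref <- read_brat_standoff(file.path(sample_dir, "sample-note.txt"),
                          file.path(sample_dir, "sample-note.ann"))
sys <- read_brat_standoff(file.path(sample_dir, "sample-note.txt"),
                          file.path(sample_dir, "sample-note.sys.ann"),
                          provenance = "system")
schema <- read_schema_config("canonical")

glance(evaluate_document(ref$annotations, sys$annotations, schema,
                         tier = "tier2", policy = "exact"))
#> # A tibble: 1 × 10
#>   tier  policy category    tp    fp    fn precision recall    f1    f2
#>   <chr> <chr>  <chr>    <int> <int> <int>     <dbl>  <dbl> <dbl> <dbl>
#> 1 tier2 exact  ALL          5     1     2     0.833  0.714 0.769 0.735

glance(evaluate_document(ref$annotations, sys$annotations, schema,
                         tier = "tier0", policy = "partial"))
#> # A tibble: 1 × 10
#>   tier  policy  category    tp    fp    fn precision recall    f1    f2
#>   <chr> <chr>   <chr>    <int> <int> <int>     <dbl>  <dbl> <dbl> <dbl>
#> 1 tier0 partial ALL          6     0     1         1  0.857 0.923 0.882
```

Read: under strict exact matching at fine granularity, 5 of 7 gold
spans are perfectly reproduced (the widened name and the missed age
fail, and the label confusion splits into a paired miss/false-alarm at
tier 2); under lenient overlap matching with categories collapsed, only
the genuinely missed age span remains a false negative.

Batch evaluation over corpora × systems × tiers × policies runs from a
YAML manifest (`score_manifest(read_manifest("manifest.yaml"))`), writes
deterministic CSV/JSON score tables, and has a thin command-line front
end:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pii_eval.R", package = "piieval"))')
Rscript $CLI simulate --out demo --n-docs 25 --seed 9   # synthetic corpus
Rscript $CLI score --manifest demo/manifest.yaml        # score it
Rscript $CLI run --template 'mytool {input} {output}' \
        --documents demo/brat/txt --out demo/sysout     # time a system
```

`tidy()`/`glance()` turn evaluation objects into metric tables and
`autoplot()` draws the per-category recall/precision/F1 panels.

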