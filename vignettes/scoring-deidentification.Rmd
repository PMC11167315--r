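---
title: "Scoring clinical text deidentification: the model behind piieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring clinical text deidentification: the model behind piieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piieval)
library(dplyr)
```

## The problem

Automated deidentification systems tag spans of protected health
information (PHI) — names, dates, identifiers, addresses — in clinical
notes so the notes can be shared for research. Comparing such systems is
harder than it sounds: every corpus and every system labels PII with its
own category vocabulary, spans rarely line up character-for-character,
and a missed name is far costlier than an over-redacted word. piieval is
a scoring engine for exactly this situation: it aligns reference (gold)
and system annotation spans per document, bridges incompatible category
vocabularies through declarative schema maps, and reports precision,
recall and F-scores at configurable granularity.

Everything operates on character offsets. An annotation is a half-open
interval `[begin, end)` counted in Unicode code points of the document
text, 0-based. Zero-length spans are rejected at validation rather than
silently dropped, because they make every overlap predicate vacuous.
CRLF and lone CR are normalised to LF before offsets are computed; that
normalisation is part of the offset contract, and converters feeding the
two supported input dialects (brat standoff, inline i2b2-style XML) must
honour it.

## Matching policies

Whether a reference span and a system span "match" depends on the
question being asked. Three policies are supported:

* **exact** — offsets must be identical. The strictest view; punishes a
  system that redacts `"Dr. Maria Lopez"` when the gold span is
  `"Maria Lopez"`.
* **partial** — any character of overlap counts. The most generous view.
* **fully contained** — the system span must cover the whole reference
  span; it may extend further on either side but not fall short. This is
  the privacy-relevant middle ground: if it holds, no PII leaks outside
  the redacted region, which a mere partial overlap cannot guarantee.

The three predicates nest — every exact match is contained, every
containing pair overlaps — so true-positive counts are monotone across
policies, a property the test suite checks on randomized inputs.

## One-to-one alignment

Within one document (annotations never match across documents), the
candidate pairs satisfying the policy — and, unless evaluation is
collapsed, sharing a scoring category — form a bipartite graph between
the reference and system sides. piieval selects a maximum-cardinality
one-to-one matching via augmenting paths. Matched pairs are true
positives; unmatched reference spans are false negatives; unmatched
system spans are false positives.

One-to-one maximum matching was a genuine design choice. Its virtues:
the conservation laws `tp + fn = |reference|` and `tp + fp = |system|`
hold in every cell by construction, counts are independent of input
order, and the policy-nesting property survives aggregation. The cost is
that a system emitting two fragments over one long gold span earns one
true positive plus one false positive — fragmented-span edge cases where
a many-to-one scorer would be more charitable. Counts are invariant
across equal-cardinality matchings; the reported pair list is made
deterministic by processing reference spans in canonical order and
preferring larger overlaps, so reports diff cleanly.

Every call produces both tallies at once: per-category counts (where a
reference of category A covered only by a system span of category B
surfaces as paired `fn(A)`/`fp(B)`, never a true positive) and collapsed
counts in which labels are ignored and any policy-satisfying pair may
match. Collapsed true positives can only exceed the per-category sum
("collapse dominance"), and returning both per call is why the engine
exposes no separate collapsed switch at the document level.

## Schemas and tiers

A schema configuration declares, per native category of one corpus or
system vocabulary, how it is located in the files (brat type field, or
the `TYPE` attribute / element name in XML) and which shared *scoring
category* it maps to at each tier:

* **tier 0** — everything is `"PII"`; category-free detection.
* **tier 1** — seven semantic groups: Address, Age, ContactInformation,
  Identifiers, Names, Occupations, Time (with corpus-specific paired
  values such as `PhoneFax` where a schema merges phone and fax spans at
  that level).
* **tier 2** — the finest division, approximating the HIPAA Safe Harbor
  categories (the shipped taxonomy has 29, including practical
  extensions such as all-ages `Age`, where strict HIPAA covers only ages
  over 89 — the 2006 schema's age rule is confined to that stricter
  notion).
* **native** — no mapping at all.

A tier value of `"unmapped"` means "this vocabulary has no analogue
here": such annotations are excluded from scoring entirely — neither
false positive nor false negative — with the exclusion counted and
logged, and a warning the first time an unknown native name is seen.
Silently imputing zero-credit would make precision meaningless for
systems whose vocabulary simply lacks a category; explicit exclusion
keeps that visible. Within every shipped schema the tiers are monotone:
natives sharing a tier-2 value share their tier-1 value, and everything
maps to `PII` at tier 0.

The file format is a deliberately small sectioned key-value dialect
(`[Native]` sections with `extract`, `tier0`, `tier1`, `tier2` keys)
defined by this package; fidelity to any other tool's configuration
syntax is a non-goal. `shipped_schemas()` lists the bundled
configurations: one per supported corpus schema, one per deidentification
system vocabulary (best-effort transcriptions; rows attested only in
system documentation are harmless because unmapped categories are
excluded), and `canonical` — the curated tier taxonomy itself, which the
synthetic generator uses.

## Metrics

From a count triple: `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`
(recall is also called sensitivity), and

$$F_\beta = \frac{(1+\beta^2)\,PR}{\beta^2 P + R},$$

with $F_1$ the harmonic mean and $F_2$ recall-weighted — apt for
deidentification, where a missed name is worse than an extra redaction.
A zero denominator yields `NA`, the *undefined* sentinel: never an
imputed 0 or 1, because "this system emitted nothing in this cell" and
"this system was wrong about everything" must stay distinguishable.
`macro_average()` skips undefined inputs and reports how many it
skipped; micro averages arise by summing count triples before computing
the metric, and corpus-level results expose both, labelled. Tables round
to four decimals for display; serialised JSON keeps full precision.

## The synthetic study

The shared-task corpora this engine is aimed at are restricted,
withdrawn or private, so the package carries its own fixture generator
instead. Each synthetic document interleaves random filler gaps with
planted PII spans labelled from the canonical tier-2 taxonomy. Because
the text is built around the spans, planted spans are non-overlapping
and in-bounds by construction (there is no infeasible-packing failure
mode), and every document passes validation. Filler is random
characters, not clinical prose: the engine is offset-based and never
inspects content, so linguistic realism would buy nothing — which is
also precisely what passing tests do *not* show. Synthetic results
demonstrate that the scoring machinery is correct, not that any real
system performs well; real notes bring fragmented spans, ambiguous
boundaries and category semantics that no generator parameter emulates.

Defaults, chosen once to resemble a mid-sized shared-task corpus and
kept fixed: 250 documents, Poisson(20) planted spans per document
(~5,000 spans, comparable to a real test split), mean span length 8
characters, mean gap 20 (minimum 2, so spans never touch), and category
weights shaped like PII frequency in clinical notes — dates and provider
names dominate, exotic identifiers are rare, every category keeps
positive weight so fine-grained cells are exercised.

The error channel degrades the reference into a "system output" with
four independent phases, each drawing from its own RNG substream derived
from the channel seed (miss, spurious, jitter, confusion — in that
order): switching one phase on or off never perturbs another phase's
draws, so, per seed, expand-only jitter provably changes no collapsed
true positive relative to no jitter.

* `p_miss` — each reference span dropped independently (default 0.2);
* `spurious_rate` — Poisson extra spans per document (default 2), placed
  inside filler gaps only, so a spurious span never overlaps a planted
  one and is a guaranteed false positive;
* `jitter_mode`/`jitter_max` — `expand_only` moves boundaries outward by
  at most `jitter_max` (default 2) characters, clipped at document
  edges; `shift` may move either boundary either way (and can break
  matches);
* `confusion` — per-category relabelling probabilities, surfacing as
  paired fn/fp at tier 2 while leaving collapsed counts untouched when
  offsets are preserved.

With no jitter or expand-only jitter, survivors still match their
references under `partial` and `fully_contained`, so collapsed tier-0
metrics have closed forms: $E[recall] = 1 - p_{miss}$ and
$E[precision] = N(1-p_{miss})\,/\,(N(1-p_{miss}) + D s)$ for $N$ planted
spans over $D$ documents at spurious rate $s$. No closed form is claimed
for shift jitter or the exact policy, and `expected_metrics()` refuses
those combinations rather than guessing. The end-to-end check runs the
full pipeline — generate, perturb, score — at the default study size and
recovers both expectations within ±0.02 absolute; at ~5,000 planted
spans the binomial standard error of recall is about 0.006, so the
tolerance is comfortable without being vacuous.

## Numerical and engineering choices

* Offsets count Unicode code points, not bytes — unambiguous arithmetic
  for overlap tests; anyone comparing byte-offset output must convert.
* Annotation tables are kept in canonical `(doc_id, begin, end,
  category)` order; serialising and re-reading reproduces the identical
  table in both dialects.
* Score tables are byte-stable: identical inputs produce identical CSV
  and JSON bytes (no timestamps, locale-independent formatting), so
  reruns diff to empty.
* Document sizes make per-document, per-category matching cheap;
  augmenting-path matching is quadratic-ish in spans per document, which
  is tiny here.
* All randomness flows through explicit seeds; no function reads or
  perturbs the caller's global RNG state.
* Batch scoring is driven by a YAML manifest (with `${VAR}` environment
  interpolation for pipelines configured that way); at tier 0 only the
  collapsed `ALL` row is emitted since per-category and collapsed
  coincide there, and at other tiers every category in the union of the
  two schemas' vocabularies gets a row — zero counts included — so the
  table's shape is a function of the manifest alone.
* External systems are run per note through a `{input}`/`{output}`
  command template with wall-clock timing reported as seconds per note
  and notes per second. Timing is hardware-dependent and start-up cost
  is not separated out, so these numbers are descriptive only and never
  asserted in tests.

Test problem sizes, chosen as a balance between coverage and a
fast-by-default suite: the matching engine is audited against
exhaustive enumeration on 500 random documents with up to six spans per
side under all three policies; conservation and collapse dominance are
audited over 1,000 randomized documents; round-trips run over 100 seeded
documents per dialect; parameter recovery runs once at the full default
study size.

## Worked example

```{r example}
sample_dir <- system.file("extdata", "sample-synthetic",
                          package = "piieval")
ref <- read_brat_standoff(file.path(sample_dir, "sample-note.txt"),
                          file.path(sample_dir, "sample-note.ann"))
sys <- read_brat_standoff(file.path(sample_dir, "sample-note.txt"),
                          file.path(sample_dir, "sample-note.sys.ann"),
                          provenance = "system")
schema <- read_schema_config("canonical")

# strict view: exact offsets, fine-grained categories
glance(evaluate_document(ref$annotations, sys$annotations, schema,
                         tier = "tier2", policy = "exact"))

# privacy view: does any redaction fully cover each gold span?
tidy(evaluate_document(ref$annotations, sys$annotations, schema,
                       tier = "tier1", policy = "fully_contained"))
```

The sample note is a handcrafted synthetic sentence (no real PHI): the
"system" output misses the age span, widens the patient name and
mislabels the provider as a patient, so exact/tier-2 scoring shows the
damage while partial/tier-0 scoring forgives everything except the
missed age.

## Known limitations

* One-to-one matching undercounts fragmented system spans relative to a
  many-to-one scorer; differences against other tools are expected in
  those edge cases.
* Only two input dialects are supported; adapting a real system's native
  output is the caller's job.
* No confidence intervals or significance tests between systems are
  computed.
* Tier-1 vocabularies are schema-relative: corpus schemas that pair
  categories (e.g. `PhoneFax`) only align with system schemas written
  against the same pairing. The canonical taxonomy carries the seven
  standard groups.
* Synthetic fixtures validate the scorer, not any deidentification
  system; conclusions about real systems require real annotated notes.
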