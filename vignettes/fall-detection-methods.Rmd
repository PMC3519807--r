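---
title: "Mining syntactic decision rules for inpatient-fall surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining syntactic decision rules for inpatient-fall surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallnlp)
```

## The problem

Hospitals detect inpatient falls mainly through voluntary incident
reports, which miss a substantial share of events and often arrive hours
after the fall. The narrative text already stored in the hospital
information system — progress notes, imaging order forms, discharge
summaries, the incident reports themselves — describes most falls, and a
text classifier over those sources can both surface unreported events and
shorten the time to detection, particularly for injurious falls that
trigger an imaging order. `fallnlp` implements such a classifier as a set
of human-readable *category decision rules* mined from a labeled corpus,
together with the surveillance statistics needed to compare document
sources: detection metrics, documentation rates, fall rates, submission
lags, injury-severity contrasts and source overlap.

## The rule model

Input text is assumed to be morphologically analyzed and dependency
parsed upstream (for Japanese clinical text this is essential: tokens are
not whitespace-separated). A parsed corpus is a tibble of morphemes with
`lemma`, `pos`, 1-based `token_index` and a `head_index` per sentence
(`0` = root, heads form a forest). Rule matching operates on lemmas, the
normalized base forms, so inflected variants of "fall" or "slip" all
match the same rule term.

A decision rule has two or three terms in one or two groups:

* within a group, `A+B` requires the two terms to occur as a **direct
  dependency pair** in one sentence. Direction is deliberately ignored
  (head→dependent or dependent→head) because the relation expressed by a
  dependency link — "support" modified by a negation, "slip" governing
  "bed" — is meaningful in either orientation and parser conventions
  differ.
* between groups, `G1 -> G2` expresses causal or temporal precedence.
  Causality is not computable from surface text, so the package
  operationalizes `->` as *strict document order*: some match of `G1`
  must precede some match of `G2`, comparing (sentence index, token
  index) lexicographically, with cross-sentence matches allowed. Clinical
  narratives describe event chains across clauses and sentences
  ("couldn't support the patient. The patient then fell…"), which is why
  the relation is not confined to one sentence. The match position of a
  dependency pair is the smaller of its two token indices.

A bare single term is not a rule: rules encode *relations* between
concepts, which is what distinguishes this approach from keyword search.
Rules are capped at three terms by default (`max_terms`); the template
shapes are `T1+T2`, `T1 -> T2`, `T1+T2 -> T3` and `T1 -> T2+T3`.

`match_rule()` implements the semantics directly for one document;
mining and classification use an equivalent vectorised matcher built on
per-document first/last match positions (every template above reduces to
an existence test "earliest match of the left part precedes the latest
match of the right part", so first/last positions are sufficient
statistics). The two implementations are cross-checked against an
exhaustive token-tuple oracle in the test suite.

## Candidate generation and selection

`enumerate_candidates()` instantiates every template whose lemmas
co-occur with the required relations in at least `min_support` positive
documents (default 5). A support floor is needed because the candidate
space is quadratic-to-cubic in vocabulary; singleton co-occurrences carry
no statistical information and would dominate the candidate list.

Each candidate is scored on the 2×2 table of document counts
(`a`/`b` positive matching/not, `c`/`d` negative matching/not) with both
the 1-df chi-square test *without* continuity correction and the
two-sided Fisher exact test (sum of hypergeometric probabilities no
larger than the observed table's, with the conventional `1 + 1e-7`
relative tolerance). The decision p-value is the Fisher p when any
expected cell count is below 5 and the chi-square p otherwise — the
standard applicability convention. A rule is selected when
`selected_p < alpha` (default 0.05) **and** it is enriched in the
positive class. The counting unit is the document: a rule either matches
a report or it does not, and the test compares the proportions of
matching documents between classes.

Degenerate tables (a zero column margin — the candidate matches every
document or none) carry no information about association and score
`p = 1`.

### Redundancy pruning and rule equivalence

After selection, a rule whose set of matched positive documents is
*identical* to that of a strictly smaller selected rule is pruned: it
adds terms without changing discriminative behavior on the training
data. The pruned rules and their kept equivalents are retained in the
`pruned` attribute of the returned rule set, and `rule_in_set()` tests
membership up to this equivalence. This matters for synthetic
benchmarks: a planted three-term pattern always co-occurs with its own
two-term dependency pair, so the pair matches exactly the same documents
and the three-term form is always pruned in its favor. Recovery of a
planted pattern is therefore assessed with `rule_in_set()`, not by string
membership in the selected table.

Ties in the output ordering are broken by decision p, then rule size,
then the rule string, making mining fully deterministic.

### Multiplicity: what raw α = 0.05 selection implies

The selection procedure tests thousands of candidates at a fixed raw
significance level with **no multiple-testing correction** — that is the
procedure this package models, and it is kept faithfully. The
consequence is a predictable false-discovery mass: about α/2 of the null
candidates end up selected (the enrichment filter halves the two-sided
rate). On a 200+200-document synthetic corpus with ~4,000 candidates,
roughly 90 chance-significant background rules join the genuinely
discriminative ones; because each of them matches common background
patterns, their *union* fires on most held-out documents and held-out
specificity collapses, even though every planted pattern is recovered
and equal-prevalence decoys are rejected. In the original workflow this
was controlled by manual curation of the mined rules into thematic
groups; curation is a human judgement and out of scope here (the
`tag_rule_category()` helper only applies user-supplied lexicons).
Users who want an uncurated rule set to generalize should tighten
`alpha`: at `alpha = 1e-4` the planted signal (p ≈ 1e-15 at 30%/1%
prevalence) survives, the chance background disappears, and held-out
sensitivity and specificity approach the planted prevalences.

## Evaluation metrics and rounding

`compute_metrics()` reports sensitivity `tp/(tp+fn)`, PPV `tp/(tp+fp)`,
specificity `tn/(tn+fp)` and the F-measure (harmonic mean of PPV and
sensitivity). A metric with a zero denominator is *undefined* and
returned as `NA` — never silently 0 or 1, which would corrupt aggregate
reports.

Published clinical tables round half-up, and running text typically
states proportions as percentages with one decimal ("86.5%") before
tabulating them at two decimals (0.87). To reproduce printed figures
exactly, reported metrics are rounded half-up at per-mille precision
first and then at the requested number of decimals; with plain one-stage
rounding the boundary case 224/259 = 0.8649 would print as 0.86 where
the published table has 0.87. `fall_rate()` (per 1,000 patient-days, two
decimals) and `data_containing_rate()` (percent, one decimal) follow the
same half-up convention at their printed precisions.

## Surveillance analytics

Fall-event streams are tibbles with one row per event: occurrence time,
WHO injury severity (`none < mild < moderate < severe`), and per source
a recorded flag and a submission timestamp (never before occurrence).

* **Lags** (`lag_minutes()`, `summarize_lags()`) are fractional minutes
  from occurrence to submission, summarised as median (25th, 75th
  percentile) using linear interpolation between order statistics
  (`quantile()` type 7). The percentile convention is not dictated by the
  statistics being emulated; type 7 is the most widespread default and is
  applied consistently.
* **Lag comparisons** (`compare_lags()`) use the two-sided Wilcoxon
  rank-sum test: the exact null distribution when the combined sample is
  at most 20 and tie-free, otherwise the normal approximation with
  tie-corrected variance and 0.5 continuity correction. This covers both
  regimes the method is used in (small worked examples; hundreds of
  events per source) with a single deterministic dispatch rule.
* **Severity contrasts** (`compare_severity()`) test the 2×K table of
  severity counts with the chi-square test, substituting Fisher's exact
  test for 2×2 tables with any expected cell below 5. Categories may be
  collapsed into contiguous groups of the severity ordering — typically
  mild versus moderate+severe, the clinically meaningful contrast when
  "none" does not occur among analyzed events. Non-contiguous groupings
  (e.g. pooling "none" with "severe") are rejected.
* **Source overlap** (`source_overlap()`, `detection_gain()`) partitions
  events by which of two sources recorded them; the detection gain of
  adding source B to source A is `100·only_B/(only_A+both)` percent.
  Events recorded by both sources deliberately contribute to both
  sources' severity histograms and lag samples, mirroring how such
  surveillance comparisons are published; the two groups are therefore
  not independent, which the analysis consumer must keep in mind.

## The synthetic generators

No clinical corpus can ship with the package, so two seeded generators
make every pipeline stage testable.

**Corpus generator** (`corpus_sim_config()`,
`generate_labeled_corpus()`). Documents have 1–5 sentences of 4–12
tokens; background lemmas follow a Zipf distribution over a reserved
vocabulary (`w001`…); each non-root token gets a uniformly random head
among the other tokens of its sentence, after which cycles in the head
graph are broken into a forest (re-rooting the smallest cycle member).
Planted patterns are inserted per document with class-specific
prevalence: dependency groups are realized as an actual head edge,
precedence by placing the first group in an earlier sentence (or earlier
token positions), and cycle-breaking never cuts a planted edge. Planted
lemmas never occur as background, so a planted rule's empirical match
rate equals its configured prevalence in expectation — the property the
recovery benchmarks rely on. When a small document has no room left for
a further pattern, a minimal extra sentence is appended rather than
silently skipping the plant, keeping prevalences exact. Defaults mirror
the emulated training collection: 277 positive and 2,313 negative
documents with the two worked-example rules planted at 30%/1%.

The generator emulates *structure*, not language: real clinical text has
topical correlation between lemmas, negation, misspellings, and genuine
partial occurrences of rule patterns (a "slip" without a "fall"). A
passing recovery benchmark therefore shows the mining machinery is
correct under known ground truth, not that real-corpus performance will
match.

**Event generator** (`event_sim_config()`,
`generate_event_stream()`). Defaults are fixed to the emulated study
conditions: 508 events over 267,301 patient-days; documentation
probabilities 1.00 (progress notes), 0.65 (incident reports), 0.125
(image orders), 0.025 (discharge summaries); severity split 492:7:9;
log-normal submission lags parameterized by median (291 min incident
reports, 73 min image orders). Moderate/severe events multiply the
image-order recording probability by 6 (capped at 1), the simplest
mechanism reproducing the clinical fact that injurious falls trigger
imaging and hence the severity shift among image-order detections. Lag
dispersions are not printed quantities; the defaults (log-sd 1.6 and
2.8) are loose fits to the reported quartiles and are config-exposed
rather than asserted. Lag medians for progress notes (120 min) and
discharge summaries (7 days) are package choices of clinically plausible
values, as is the uniform occurrence process over a 365-day period. A
single log-normal cannot reproduce the reported bimodal image-order lag
shape (a peak at one hour and another past 18 hours, from delayed
symptom onset); the dispersion default absorbs this as heavy right skew.

## Numerical choices and degenerate inputs

* Fisher two-sided p sums hypergeometric probabilities
  `<= p_observed * (1 + 1e-7)`, matching the tolerance used by standard
  implementations; the test suite verifies equality with
  `stats::fisher.test()` and with direct enumeration for every table of
  total size ≤ 40.
* Empty rule sets classify everything negative with a warning rather
  than erroring: an over-strict `alpha` should degrade gracefully in a
  pipeline.
* Empty documents match no rule; empty corpora round-trip through the
  file formats.
* Rule-set files store p-values with 17 significant digits, so
  write→read round-trips are bit-exact.
* Identical lag samples yield p = 1 (the continuity-corrected z is 0).
* All generators are deterministic given their seed
  (`withr::with_seed`), and CLI outputs carry provenance headers
  (version, subcommand, parameters, seed).

## Problem sizes used in the checks

The shipped benchmarks use 200+200-document corpora with a planted
pattern at 30%/1% prevalence and an equal-prevalence decoy at 10%/10%,
20 seeded mining replicates, and 10,000-event streams; statistical
recoveries are asserted against 99% binomial bounds and lag medians
within 10%. These sizes give the recovery probabilities comfortable
margins while keeping a full run in minutes on one core. Decoy rejection
is a per-replicate 1 − α/2 event by construction, so occasional single
failures across 20 replicates are expected behavior, not regressions.

## Known limitations

* No morphological analysis or dependency parsing is included; garbage
  parses in, garbage rules out.
* `->` is surface order, not causality; a narrative that mentions the
  fall before its cause will match the reversed rule.
* No negation scope handling beyond negation morphemes appearing as rule
  terms (as in `sasaeru+nai`).
* Raw-α selection without correction is faithful to the modeled
  procedure but statistically permissive; uncurated rule sets need a
  tightened `alpha` to generalize (see the multiplicity section).
* The severity/lag comparison treats dual-source events as members of
  both groups, as published; it is a descriptive contrast, not an
  independent-samples inference.
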