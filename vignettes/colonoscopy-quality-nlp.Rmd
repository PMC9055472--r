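---
title: "Rule-based extraction of colonoscopy quality indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based extraction of colonoscopy quality indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonlp)
library(dplyr)
```

## The problem

Colonoscopy quality assurance rests on indicators that must be assembled
from two free-text documents: the endoscopist's colonoscopy report and the
pathologist's report on the biopsied specimens. The adenoma detection rate
(ADR) — the proportion of colonoscopies finding at least one adenoma — and
its sessile serrated lesion analogue (SDR) are the indicators most strongly
tied to post-colonoscopy cancer outcomes, and the recommended surveillance
interval depends on a rollup of every polyp's size, multiplicity and
histology. Computing these by hand means reading both reports for every
procedure; `colonlp` automates the pipeline with deterministic,
inspectable rules.

## Pipeline model and assumptions

The pipeline assumes the input schema already separates the findings
section of the colonoscopy report and the diagnosis section of the
pathology report (no section detection or OCR is attempted). Three stages
follow:

1. **Linking.** The findings section is split into sentences (newline or
   period-plus-whitespace boundaries; decimals such as "1.2 cm" cannot
   split because their period is never followed by whitespace). Sentences
   carrying a biopsy-related phrase — a `biopsy_marker` lexicon concept
   such as *bx*, *polypectomy*, *EMR*, *removed*, or an explicit specimen
   label like `#2` — are numbered in order of appearance, and the diagnosis
   section is split into specimens at enumerators ("1.", "1)", "#1"). The
   i-th biopsy sentence is paired with the i-th specimen. When sentences
   carry usable explicit labels, label-based pairing overrides sequence
   order (labels are stronger evidence; the sequence rule is the default
   convention). If the sentence and specimen counts differ, the surplus
   items are emitted with `mismatch_flag = TRUE` and processing continues:
   documentation errors are a fact of real report streams and must be
   surfaced, never silently truncated.

2. **Extraction.** Concept matching is lexicon-driven: surface forms are
   NFKC-normalized (mixed-script reports routinely carry full-width
   characters), lower-cased and matched at word boundaries; overlapping
   candidates are resolved longest-span-first with a leftmost tie-break, so
   *tubulovillous adenoma* is never shadowed by its *adenoma* substring.
   Locations map to ten anatomical segments; the left colon runs from the
   rectum to the splenic flexure and the right colon from the transverse
   colon to the cecum. When only an insertion depth is documented, a
   distance of at least 60 cm from the anal verge is attributed to the
   right colon; an explicit segment name always wins over a distance,
   which is treated as the fallback convention. Sizes convert cm to mm and
   resolve ranges ("5-7 mm") to their maximum — conservative for the
   1 cm advanced-lesion threshold. The endoscopic (findings-section) size
   is authoritative; pathologic size is not extracted. Histology comes from
   the specimen text: adenomas (tubular / tubulovillous / villous),
   serrated polyps (hyperplastic, SSL — with SSA/P surface forms mapped to
   SSL by nomenclature synonymy — and traditional serrated adenoma) and
   carcinoma, with dysplasia grade carried separately. Negation is handled
   as a cue-in-clause rule: a cue ("no", "without", "negative for")
   suppresses concepts up to the next comma or period, which is adequate
   for short templated report sentences ("tubular adenoma, no dysplasia")
   and deliberately avoids general negation-scope modelling.

3. **Summarization and indicators.** Findings roll up to one row per
   procedure. An adenoma is advanced when it is at least 10 mm, carries
   high-grade dysplasia, or has villous features (tubulovillous counts as
   villous features, the standard clinical convention); an SSL is advanced
   when at least 10 mm or dysplastic at any grade. A finding with
   multiplicity *c* contributes *c* lesions to its class count. Carcinoma
   never sets the adenoma flags (the categories are disjoint), and findings
   with unknown side count toward presence but not toward the side
   categories. Missing size never satisfies a size criterion: an adenoma
   with no documented size is treated as below 1 cm, the only option that
   does not invent advanced lesions.

## The surveillance decision table

Interval assignment follows the 2020 US Multi-Society Task Force
recommendations, transcribed into a TSV decision table shipped with the
package (`system.file("extdata", "usmstf2020_rules.tsv", package =
"colonlp")`). The table is data, not code — one rule per row with a
priority, a vectorized predicate over the summary columns and a target
group — so institutions can audit or replace it. Rules are evaluated in
priority order and the first match wins:

```{r}
as.data.frame(default_decision_rules()[, c("priority", "rule_id",
                                           "interval_group")])
```

Carcinoma maps to `refer` rather than one of the six groups: the guideline
has no cancer interval and such patients leave the screening pathway.
Hyperplastic polyps of at least 10 mm fall in the 3-5-year group, following
the guideline. For mean-interval reporting the range groups map to their
midpoints (3-5 → 4, 5-10 → 7.5, 7-10 → 8.5 years); the mapping is a plain
named vector (`default_interval_mapping()`) because any point value for a
range recommendation is a reporting convention, not a clinical fact.
Per-endoscopist mean intervals average over non-refer assignments, with the
refer count reported separately, since `refer` has no defensible numeric
value.

## Indicator conventions

Rates are proportions of procedures; reported percentages are rounded to
0.1. Between-endoscopist spread statistics (`range_stats()`) — the max–min
difference and the max/min fold ratio — are computed on that 0.1-rounded
percentage scale, i.e. on the rates as reported, so the printed spread is
always consistent with the printed per-endoscopist table; the fold ratio is
undefined when the minimum rate is zero. Endoscopist banding uses inclusive
middle edges (ADR "30%-45%" means [30, 45]). Per-endoscopist profiles
require strictly more than 500 procedures by default, and the default
cohort is patients aged 50 or older. Group comparisons use the chi-square
test without continuity correction (the plain sum of squared
observed-minus-expected over expected) and the two-sample t test.

## Evaluation harness

Performance against gold annotations is scored with recall, precision,
accuracy and F1 (the harmonic mean of precision and recall), per variable
and — for multiclass variables such as side categories, count bins and
interval groups — one-vs-rest per category. Degenerate denominators follow
least-surprise conventions, unit-tested explicitly: with no predicted
positives, precision is 1 when there was also nothing to find and 0
otherwise; F1 is 0 whenever there are errors but no true positives, and 1
for a vacuously perfect variable. Procedures missing from the gold set are
excluded and counted. Metrics are reported to two decimals by default.

## What the synthetic generator emulates — and what it does not

`synth_config()` / `generate_corpus()` produce paired reports whose
*structure* matches clinical practice: a findings section in which every
biopsied polyp occupies one sentence containing a biopsy phrase, and an
enumerated pathology diagnosis section listing specimens in the same order.
Default prevalences are set to a screening population: five endoscopist
profiles spanning ADR 0.16–0.56 and SDR 0.004–0.066 (the spread reported
across real screening programs, and wide enough to exercise banding and
range statistics), an 8% advanced fraction among adenoma-positive
procedures and 16% among SSL-positive ones, sizes mostly 2–9 mm with
advanced lesions at 10–20 mm, incidental hyperplastic polyps in 18% of
procedures, rare TSAs (0.4%) and carcinomas (0.15%). Locations cover all
ten segments with a right-sided tilt, and 12% of polyps are documented
only as a distance from the anal verge. Abbreviations (S-colon, bx, ...)
appear at a configurable rate, as do explicit `#k` specimen labels,
distractor sentences and range-style size wording. Two noise channels are
gold-flagged: specimen-count mismatches (a dropped specimen) and
distractors. Generation draws from a single seeded RNG stream in procedure
order, so a (config, seed) pair is reproducible byte for byte.

The generator deliberately does **not** model: Korean or mixed-script
narrative (the lexicon format supports other languages, but no Korean
entries are shipped, since no such vocabulary inventory is public),
free-form clinical prose beyond the template inventory, morphology
classifications, bowel-preparation or cecal-intubation statements, and
pathology reports that disagree with the endoscopic impression. A perfect
round-trip on clean synthetic corpora therefore demonstrates the internal
consistency of the rule system — that extraction inverts the rendering
grammar exactly — not performance on any real report stream, where
vocabulary coverage is the binding constraint and must be extended through
the lexicon TSV.

## Numerical and testing choices

Sentence/specimen pairing, rollup and interval assignment are pure
functions of their inputs; ties in maximal-span matching break leftmost;
`which.min`-style ties in range statistics keep the first endoscopist in
table order. The test suite exercises round-trip exactness on a clean
corpus of 2,000 procedures, mismatch detection on 1,000 procedures with a
10% injection rate, decision-table totality and monotonicity on 10,000
randomized summaries, and detection-rate recovery against the configured
profiles under an exact 99% binomial interval (`qbinom(c(0.005, 0.995), n,
p)/n`) — sizes chosen to keep each property statistically meaningful while
the whole suite runs in about a minute on one core. The bundled 10-year
example counts (25 endoscopists, 54,562 procedures) drive the indicator
arithmetic checks; their band totals include a handful of procedures
outside the six interval groups, so within-band percentages sum slightly
under 100.

## Known limitations

* Lexicon coverage is the accuracy ceiling: unlisted surface forms are
  invisible, and no fuzzy matching or embeddings are attempted by design.
* Negation scope is clause-local; discontinuous or long-range negation is
  out of scope.
* A sentence naming several segments is expanded to one finding per
  segment and flagged for review rather than resolved.
* Per-patient deduplication across repeat procedures is out of scope; the
  unit of analysis is the procedure.
* The decision table covers the six interval groups plus refer; piecemeal
  resection, family history and incomplete-examination modifiers are not
  modelled.
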