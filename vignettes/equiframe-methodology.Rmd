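---
title: "Scoring health policies for human-rights coverage: methodology and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring health policies for human-rights coverage: methodology and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiframe)
```

## The rubric

`equiframe` implements a standardized rubric for appraising how strongly a
health policy document commits to core concepts of human rights, and for
whom. The framework crosses **21 Core Concepts** (non-discrimination,
access, autonomy, participation, protection from harm, capacity building,
cultural responsiveness, individualized services, and so on) with **12
Vulnerable Groups** (people with limited resources, displaced populations,
persons with disabilities, youth, the aged, ethnic minorities, people with
chronic illness, ...). Every reference a document makes to a concept is
scored for quality of commitment:

1. concept only mentioned;
2. concept mentioned and explained;
3. specific policy actions identified to address the concept;
4. intention to monitor the concept expressed.

A reference is recorded *for* the vulnerable group it concerns; a
statement addressing the total population ("all people", "everyone") is
recorded in a distinguished **Universal** column. A concept genuinely
irrelevant to a document may be marked *not applicable*. Two raters score
each document independently and resolve differences by discussion to a
consensus.

The document's **score matrix** is the 21 × (12 + Universal) grid of best
scores: where several references feed one cell, the top quality score is
kept (the max rule). Three indices summarize the matrix — Core Concept
Coverage (concepts mentioned / 21), Vulnerable Group Coverage (base
groups mentioned / 12; Universal never counts) and Core Concept Quality
(concepts with best score ≥ 3 / 21) — and the Overall Summary Ranking
classifies the document *High* (all three indices ≥ 50%), *Moderate*
(exactly two) or *Low* (otherwise).

Assumptions worth stating plainly: the rubric appraises *policy on the
books*, not implementation; the three indices weight all concepts and all
groups equally; and the 50% criterion is a convention, adjustable through
the `threshold` argument but left at its canonical default everywhere in
this package.

## What is automated and what is not

The quality distinctions between levels 2, 3 and 4 (explanation, action,
monitoring) are judgments this methodology assigns to human raters.
Automation here is therefore deliberately asymmetric:

- `detect_mentions()` *proposes* candidate mentions by key-language
  matching — exact phrase, case-insensitive, on word boundaries, with no
  stemming. This favours reproducibility over recall; the editable lexicon
  (see below) is where recall is tuned, and raters remain the arbiter.
- `pair_mentions()` attaches each concept mention to the group mentioned
  in the same sentence, or to Universal if only a universal phrase is
  present.
- Quality scores 2–4 always come from annotations (rater worksheets read
  back with `read_annotations()`), never from text heuristics.

The **unit of analysis** for pairing is the sentence. The rubric itself is
silent on pairing scope — raters read whole documents — so the package
uses the smallest unit in which a concept and a group are plausibly
co-referential, which is also the most auditable choice; `window = n`
widens the rule to ±n sentences when a corpus is drafted in a style that
separates subject and beneficiary. A concept mention with no group and no
universal phrase in scope defaults to the Universal column
(`universal_default = TRUE`), following the rubric's rule that
population-wide statements address everyone; setting it `FALSE` instead
reports such mentions unpaired, for corpora where a bare concept mention
should not be presumed population-wide. Both behaviours are explicit
because the original practice did not record which was used.

## The lexicon is configuration, not code

The canonical concept and group rosters live in the framework's manual,
and applying the framework to a new country may add country-specific
groups. `load_framework()` therefore reads the whole lexicon — ids, names,
definitions, key questions, key phrases, universal phrases — from a YAML
file; the shipped default carries the canonical 21 + 12 rosters with a
seed phrase lexicon that users are expected to edit. Validation enforces
unique ids, non-empty phrase lists, and the canonical cardinalities
(warning by default, error under `strict = TRUE`, so a deliberately
reduced teaching framework still loads). Country-specific groups are
additive: they gain matrix columns but never alter the base-12 coverage
denominator, keeping cross-country indices comparable.

Phrase ambiguity is policed asymmetrically, by design: a phrase shared by
two *concepts* is permitted but flagged by `phrase_conflicts()` (concept
coverage tolerates double counting candidates — raters resolve it), while
a phrase serving two *groups*, or a group and the universal category, is a
configuration error, because group-coverage denominators must be
unambiguous.

## Sentence segmentation

`segment_sentences()` is a deterministic rule set: a boundary is `.`, `!`
or `?` followed by whitespace and an upper-case letter or digit, with a
fixed abbreviation list ("e.g.", "i.e.", "Dr.", "No.", "Fig.", ...)
suppressing false splits. Spans are 0-based half-open character offsets;
concatenating spans and inter-span gaps reconstructs the input exactly
(property-tested), so every excerpt a rater sees can be traced to exact
coordinates. The trade-off versus statistical segmenters is deliberate:
identical input must yield identical candidate worksheets across machines
and sessions. Single-letter "sentences" such as initials in author lists
will over-split; for policy prose this is rare and harmless, since
segmentation errors can only move a candidate's sentence index, and raters
confirm every candidate against the verbatim excerpt.

## Numerical choices

- **Rounding.** Printed percentages use half-away-from-zero rounding
  (`round_half_up()`): 1/12 → 8.3 at one decimal, 8/21 → 38 at integer
  precision. (A small epsilon keeps decimal halves like 8.35 on the up
  side despite binary representation.) Display precision is an option
  (`digits`, default 1) because published tables mix one-decimal, integer
  and two-decimal styles.
- **Thresholds on full precision.** The ranking always uses
  full-precision index values, never the rounded display values; with a
  50% criterion and denominators 12/21 the two can only disagree through
  rounding artefacts, which this rule excludes.
- **Denominators.** Defaults stay fixed at 21 and 12 even when concepts
  are marked not applicable — the index stays "out of the 21". Passing
  `cc_denominator = NULL` excludes not-applicable concepts instead; the
  summary records the denominator actually used, since the two
  conventions are both defensible and must not be mixed silently.
- **Degenerate inputs.** An empty document has zero sentences (not an
  error); an empty annotation set gives an all-`NA` matrix whose indices
  are 0/0/0 and ranking *Low*; mixed scored + not-applicable annotations
  for one concept are an error, because that is a rater disagreement for
  the reliability workflow, not something aggregation may resolve.

## Reliability and consensus

`compare_raters()` reduces each rater's set to per-cell outcomes on
{absent, 1, 2, 3, 4, NA} and compares them over the **union of touched
cells** — comparing the full 21 × 13 grid would inflate agreement through
the many cells neither rater marked (`universe = "full"` is available,
documented as such). Concept-level not-applicable marks are compared once
per concept, not once per grid cell. Two statistics are reported: raw
cell agreement, mirroring the original practice of comparing evaluations
directly, and Cohen's kappa over the same outcome categories for
chance-corrected modern use (the closed form is implemented directly and
cross-checked in the tests against an independent implementation). No
numeric agreement target is asserted anywhere: the methodology reports
reliability, it does not gate on it. `build_consensus()` requires an
explicit resolution for every discrepancy — quality value, "absent",
not-applicable, or "adopt rater A/B" — and refuses to auto-merge,
mirroring the discussion-to-consensus step.

## The synthetic corpus generator

Real scored policy corpora are not redistributable, so validation runs on
synthetic documents with planted ground truth. A `generation_plan()`
fixes planted (concept, column, quality, n-mentions) cells, extra
universal-phrase sentences, distractor sentences and a seed;
`generate_document()` renders each planted cell through a quality-specific
sentence template (mention / explanation / action verb / monitoring
clause), each sentence containing exactly one concept phrase and one
group-or-universal phrase, shuffled deterministically. The plan is its own
oracle: the expected indices and ranking are computed analytically from
the plan, independent of the pipeline under test. Two properties make the
accuracy assertions exact rather than statistical: template and
distractor vocabulary are disjoint from every default key phrase (so
precision on synthetic text is exactly 100%), and ground-truth annotations
carry the planted quality (the generator never pretends text→quality
inference works).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: paraphrase and synonymy beyond the lexicon
(real recall depends on lexicon curation), concept–group co-reference
across sentence boundaries, tabular/bulleted policy structure, OCR noise,
and rater disagreement arising from genuine interpretive ambiguity.
Pipeline recovery on synthetic corpora validates the *machinery* (
detection, pairing, max-rule aggregation, indices, ranking), not the
lexicon's coverage of real policy prose.

Validation sizes, chosen to exercise the space while keeping the default
suite fast: 100 seeded random plans (up to 12 planted cells, 0–3 universal
extras, 0–5 distractors each) for end-to-end recovery, 200 random
matrices against a recount oracle, 1,000 random matrices for the
quality ≤ coverage invariant, and the 51 published index triples for the
ranking rule and country tallies.

## Benchmarking

`benchmark_country()` orders policies by ranking then Core Concept
Quality descending — published tables are only roughly sorted, so the
package fixes a deterministic order and offers `sort = FALSE` to preserve
input order — and tallies High/Moderate/Low. The shipped
`reference_policy_indices()` dataset (51 policies across Malawi, Namibia,
South Africa and Sudan) reproduces all four published tally sets under
this rule, which is the package's standing regression check that the
ranking logic matches the methodology as practised.

## Known limitations

- Key-language detection is lexical; a policy committing to a concept in
  unlisted wording yields no candidate. The lexicon is editable precisely
  because recall is a curation problem.
- One language per framework config; no multilingual matching.
- Input is plain text: PDF/Word extraction and OCR are out of scope.
- At most two raters per document, matching the dual-rater design.
- The 1–4 scale is ordinal but the indices treat quality as the binary
  "≥ 3"; alternative weightings are not implemented beyond the threshold
  parameter.
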