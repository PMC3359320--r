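# equiframe

Content analysis of health policy documents against human-rights Core
Concepts and Vulnerable Groups, following the EquiFrame methodology.

Health policies set the context in which services are delivered; whether
they commit — explicitly, and for the people most at risk — to rights such
as non-discrimination, access, autonomy or protection from harm is
something that can be read off the policy text itself. `equiframe` is for
health-policy researchers and analysts who want to do that reading in a
standardized, reproducible and benchmarkable way: it scores a policy
document against **21 Core Concepts of human rights** and **12 Vulnerable
Groups**, computes three summary indices and an overall High/Moderate/Low
ranking, and compares policies within and across countries.

## The method

Two raters independently read a policy. Wherever a Core Concept is
addressed for a Vulnerable Group (or for the total population — a
*Universal* reference such as "all people" or "everyone"), the commitment
is scored on a 1–4 quality scale:

| score | meaning |
|---|---|
| 1 | concept only mentioned |
| 2 | concept mentioned and explained |
| 3 | specific policy actions identified to address the concept |
| 4 | intention to monitor the concept expressed |

Scores populate a 21 × (12 + Universal) matrix; when a cell receives
several references, the top quality score is kept (max rule). A concept
irrelevant to the document may be marked not applicable. From the matrix,
three indices are computed (denominators 21, 21 and 12):

- **Core Concept Coverage** = 100 · (# concepts mentioned) / 21 — the
  Universal column counts;
- **Vulnerable Group Coverage** = 100 · (# base groups mentioned) / 12 —
  Universal references and country-specific extra groups do *not* count;
- **Core Concept Quality** = 100 · (# concepts with best score ≥ 3) / 21;

and the **Overall Summary Ranking**: *High* if all three indices ≥ 50%,
*Moderate* if exactly two are, *Low* otherwise.

The package adds the scaffolding this workflow needs in practice: a
configurable YAML lexicon (concepts, groups, key phrases, universal
phrases), deterministic sentence segmentation, key-language candidate
detection to draft rater worksheets (detection proposes mentions — quality
judgments 2–4 stay human), dual-rater comparison (raw cell agreement and
Cohen's kappa) with explicit consensus resolution, country benchmark
tables, and a synthetic policy-corpus generator with planted ground truth
for end-to-end validation.

## Worked example

```r
library(equiframe)
fw <- load_framework()   # shipped default: 21 concepts, 12 groups

text <- paste(
  "The ministry shall implement specific actions to advance access for persons with disabilities.",
  "Privacy and confidentiality are guaranteed for everyone.",
  "An intention to monitor non-discrimination for refugees is stated, with annual reporting of progress.")
doc <- policy_document(text, doc_id = "example-policy")

pairs <- pair_mentions(detect_mentions(doc, fw))
pairs[, c("concept_id", "column_id", "sentence_index")]
#> # A tibble: 3 × 3
#>   concept_id         column_id             sentence_index
#>   <chr>              <chr>                          <int>
#> 1 access             disabled                           1
#> 2 privacy            universal                          2
#> 3 non_discrimination displaced_populations              3
```

The rater confirms each candidate pair and assigns its quality (here 3 =
action stated, 2 = explained, 4 = monitored); the matrix and summary
follow:

```r
ann <- tibble::tibble(rater_id = "rater-1", doc_id = pairs$doc_id,
  concept_id = pairs$concept_id, column_id = pairs$column_id,
  quality = c(3L, 2L, 4L), evidence = pairs$evidence,
  sentence_index = pairs$sentence_index)
summarize_policy(build_matrix(ann, fw), fw)[,
  c("doc_id", "vg_pct", "cc_pct", "cc_quality_pct", "ranking")]
#> # A tibble: 1 × 5
#>   doc_id         vg_pct cc_pct cc_quality_pct ranking
#>   <chr>           <dbl>  <dbl>          <dbl> <fct>
#> 1 example-policy   16.7   14.3            9.5 Low
```

Two of twelve groups (16.7%), three of 21 concepts (14.3%) and two
concepts at quality ≥ 3 (9.5%): all three indices fall below 50%, so the
document ranks *Low*. A second rater who scored the first cell 1 instead
of 3 would be compared like this:

```r
ann2 <- within(ann, {rater_id <- "rater-2"; quality[1] <- 1L})
compare_raters(ann, ann2, fw)
#> <equiframe_comparison> example-policy : rater-1 vs rater-2
#>   agreement 0.667 (2/3 cells), kappa 0.571, 1 discrepancies
```

`reference_policy_indices()` ships the published summary indices of 51
health policies from Malawi, Namibia, South Africa and Sudan;
`benchmark_country()` turns per-policy summaries into the country tables
with High/Moderate/Low tallies. A command-line front end
(`system.file("cli", "equiframe.R", package = "equiframe")`) exposes
`detect`, `score`, `compare`, `consensus`, `benchmark` and `generate`
subcommands, each writing a machine-readable run log.

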