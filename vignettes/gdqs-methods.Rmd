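---
title: "Methods: the operationalized GDQS instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the operationalized GDQS instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdqsr)
library(dplyr)
```

## The instrument

The Global Diet Quality Score (GDQS) scores a diet by placing the grams
consumed from each of 25 food groups into broad quantity bands (low /
middle / high, plus very-high for high-fat dairy) and summing
group-and-band-specific points. Collecting the gram quantities with a full
quantitative 24-h recall is impractical for large surveys, so the
operationalized instrument replaces weighed quantities with a set of ten
hollow cubes of fixed side lengths: the respondent visualizes the combined
volume of everything they consumed from a food group during the previous
day and night and picks the closest cube. A mean density per food group
(g/cm³) converts cube volumes back into grams, which is what makes a shared
cube set able to represent gram cutoffs across very different foods.

This package implements the full data path of that instrument —
classification, quantity capture, scoring — and, separately, the design
pipeline that produced the cube set in the first place.

## Taxonomy and the dairy split

During collection the high-fat dairy group is split into *hard cheese* and
*other* (milk, yogurt, soft cheese): their densities differ too much for a
single density to be honest. The collection taxonomy therefore has 26
groups and 54 cutoffs; reporting recombines the two subgroups, returning to
the validated 25 groups and 51 cutoffs. Hard-cheese grams are multiplied by
6.1 (milk equivalents) before the merged amount is categorized against the
reporting group's original cutoffs (35 / 140 / 734 g).

Liquid oils carries two categorical cutoffs but no gram values and no
cubes: respondents cannot recall oil amounts, so its band is inferred from
three interview flags (home deep-frying with pourable oil, ≥2 mixed dishes,
pouring/using oil), with one mixed dish mapping to the middle band. The
no-trigger case is not specified by the instrument description; this
package defaults it to *low*, the conservative choice for an unobserved
quantity.

The shipped configuration (`gdqs_config_dir()`) is a transcription of the
published cutoff, cube and density tables. The printed operationalized
grams are treated as authoritative; cube sides are nominal (they are
rounded to the millimetre, which is why `cutoff_consistency_report()` shows
a systematic 2–5% drift between printed grams and density × cube volume).
The two fish-and-shellfish cutoffs deviate by roughly 20–25% from
density × volume; no published rationale exists, so the package records the
outliers rather than "fixing" them, and the consistency property in the
test suite exempts exactly those two rows.

```{r consistency}
rep <- cutoff_consistency_report(load_taxonomy())
arrange(rep, desc(rel_deviation)) |> head(4)
```

## Interview state machine

The interview is modelled as seven monotone steps: (1) free listing by
eating occasion, (2) mixed-dish decomposition into (main) ingredients,
(3) probe and manual classification, (4) deep-fried questions,
(5) caloric-sweetener probe, (6) per-group read-back and cube capture,
(7) finalization. The published description fixes the content of the steps
but not their exact machine-readable order; this ordering is the package's
reconstruction, chosen so that every operation's preconditions (e.g.
"classification complete before read-back") are expressible as a step
check. Operations invoked at the wrong step fail with a
`gdqs_session_error`.

Purchased deep-fried items are dual-classified: they stay in their original
group and are additionally tagged to the purchased-deep-fried group, and
they contribute to both groups at read-back and cube capture. Whether
home-deep-fried foods should also dual-classify is unstated; they do not
here — only the oil flags carry that information. Free-text items (absent
from the master database) must be manually classified in step 3 and retain
a `free_text_manual` provenance flag.

When a selected cube sits exactly on a group's cutoff, the interview
requires the borderline confirmation ("as big or bigger" vs "smaller");
the answer resolves the category upward or downward. Cubes 1 and 10 carry
no cutoffs by design and always map to the extreme categories.

## Fuzzy search

The published instrument names approximate string matching but no metric.
The package uses a normalized edit-distance ratio over lowercase names and
aliases with an inclusion threshold of 0.6; an exact case-insensitive match
scores 1, and a prefix match scores 0.99 × (prefix ratio), which makes
type-ahead prefix hits rank above non-prefix fuzzy hits while keeping exact
matches first. Ties break by `entry_id`, so results are independent of
database row order. Automatic matching during free listing requires a score
of at least 0.8; anything weaker becomes a free-text item rather than a
silent misclassification.

## Quantity estimation choices

The gram point estimate for a selection is the *full* volume of the chosen
cube times the group's mean density — not a midpoint between adjacent
cubes — because the respondent is instructed to pick the cube closest to
the visualized volume; the cube is the estimate. For the merged dairy
group, categorization happens in the gram domain (6.1 × cheese + other vs
35/140/734) because the milk-equivalent conversion is specified in grams;
how to combine two reported subgroups is otherwise unstated, and additive
grams is the package's decision.

## The density-derivation pipeline

The cube set was designed from eleven quantitative 24-h recall datasets
(ten LMIC, one HIC; women 15–49 y). Those datasets are not public, so the
package re-implements the procedure and validates it on synthetic data:

1. keep only each respondent's first recall;
2. per dataset and group, compute each food's share of the group's gram
   total across all women;
3. rank the top 5 foods per dataset and group (ties: larger gram
   contribution, then lexicographic name — the publication states no
   tie-break);
4. pool ranked foods across datasets (up to 55 per group), compute mean
   ranks, and keep the 10 lowest-mean-rank foods as the group's
   representatives; the group density is the simple mean of their
   densities.

Mean rank is computed over only the datasets in which a food was ranked;
how the original derivation treated foods absent from some top-5 lists is
unstated, so the penalizing alternative (`absent_rank`) is exposed as an
option rather than silently chosen.

Cutoff-to-cube conversion divides each original gram cutoff by the group
density (`volume = g/ρ`, `side = 10·volume^{1/3}`). The hard-cheese
cutoffs are printed in milk equivalents, so they are divided by 6.1 before
conversion — omitting this places the cheese cutoffs on visibly wrong
cubes, and restoring it is what makes the low/middle cheese cutoff land on
the second-smallest cube. The 52 resulting sides are clustered into 8 core
cubes by 1-D agglomerative clustering (complete linkage — the publication
says only "grouping subsets similar in size"), each core cube taking the
mean side of its members, with 18 mm and 100 mm flank cubes appended.
The authors' exact grouping is unrecoverable; the test suite claims only
plausibility — at least 6 of the 8 derived core sides within 3 mm of the
printed sides — which the shipped configuration meets.

```{r design}
tidy(derive_cube_design(load_taxonomy()))
```

## Scoring

Point values per (group, category) are deliberately *configuration*: they
belong to the validated metric definition published separately, and the
package does not assert them. `example_point_table.csv` is a toy table
(healthy 0/1/2, unhealthy 2/1/0, unhealthy-in-excess 0/2/0) used by tests
and examples only. Unreported groups score at *low*; the positive
submetric sums healthy groups, the negative submetric the unhealthy and
unhealthy-in-excess groups; the total is their sum. Dual-classified
deep-fried items contribute to both their groups at scoring time — the
published text specifies dual classification for the density work and the
application's classification step, and the package extends it to scoring
as the consistent reading.

## Synthetic data: what it does and does not establish

The generators produce structurally faithful inputs, not realistic diets:

* `gen_master_db()` builds a database from the published representative-food
  vocabulary, with probed entries (bread → refined/whole grains, milk →
  high-/low-fat dairy) and mixed dishes.
* `gen_consumption_datasets()` defaults to the published design's scale
  where stated — 11 datasets, top-5 ranks, 10-food representative sets —
  and to field-plausible values where not: 60 women per dataset (enough
  for shares to stabilize within the ±5-point tolerance, small enough for
  fast tests; the real surveys are 10–100× larger), 15 foods per group,
  log-normal gram amounts (σ_log = 0.4), per-dataset Dirichlet food
  weights so that different "countries" favour different foods — without
  this, every dataset ranks the same five foods and the pooled candidate
  sets collapse. Food densities are drawn uniformly on 0.4–1.1 g/cm³, the
  range spanned by the published group densities.

Green tests therefore establish that the *procedures* are implemented
faithfully (against brute-force oracles and the published design
constants), not that any particular population's diet is reproduced — the
latter would require the original survey datasets, which are out of scope.

## Numerical notes and limitations

* Categorization uses "below the cutoff" vs "equal to or above": a gram
  amount exactly at a cutoff falls in the upper band, matching the
  borderline rule's "as big or bigger" resolution.
* The gram cutoffs' printed rounding is inconsistent across rows
  (8.52 → 9 but 13.78 → 13), so no rounding rule is asserted anywhere.
* All randomness is seed-driven; every generator is deterministic given its
  seed, and the CLI writes a manifest with output hashes.
* The per-group two-boundary cross-check (cube category vs gram category)
  covers the 23 two-boundary cube-assessed groups; the three-boundary dairy
  subgroups are covered by the merge tests instead.
* Not implemented, by design: the mobile UI, nutrient-adequacy estimation,
  regression sensitivity analyses on external cohorts, per-country cutoff
  adaptation, and the published point values.
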