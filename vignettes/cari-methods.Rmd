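---
title: "CARI scoring, the Food Security Index, and CHAID segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CARI scoring, the Food Security Index, and CHAID segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariseg)
```

This vignette documents the statistical machinery behind `cariseg`: the
three component indicators, the index combination and its rounding rule,
the chi-square reporting layer, the CHAID segmentation engine, and the
synthetic-survey generator, together with the numerical and design choices
that a user auditing results should know about.

## The three component indicators

**Food consumption score.** `compute_fcs()` returns the weighted sum of
0–7 weekly consumption days over eight food groups. The default weights
(staples 2, pulses 3, vegetables 1, fruits 1, meat/fish/eggs 4, dairy 4,
sugar 0.5, oil/fat 0.5) are the standard WFP instrument's; the survey this
package emulates adapted the questionnaire's food items to the local diet
but published only the category cut-offs, so the group composition and
weights are config-overridable (`indicator_config(food_groups = …)`) while
defaulting to the unmodified WFP scheme. With these weights the score
ranges over 0–112 on a 0.5 grid. The half-point grid is why the published
category phrasing ("0 to 28", "28.5 to 42") is coherent: `categorize_fcs()`
implements poor iff `fcs <= 28`, borderline iff `28 < fcs <= 42`,
acceptable above — the unique convention consistent with both phrasings on
half-point scores.

**Economic vulnerability.** `compute_pwfe()` is the food share of total
household spending, in `[0, 1]`. The published band wording fixes the outer
conventions ("less than 50%", "more than 75%"); the inner boundaries are
not stated, so the package adopts left-closed bands with 0.75 kept in the
third band — `[0, .5)`, `[.5, .65)`, `[.65, .75]`, `(.75, 1]` — making
"more than 75%" strict. This is a documented convention, not an empirical
claim; all four boundaries are pinned by tests. A household with zero
total spending has an undefined share and is treated as incomplete rather
than guessed at.

**Livelihood coping.** Each of ten coping-strategy items carries a severity
tier, stress < crisis < emergency; `classify_coping()` returns the maximum
tier among answered-yes items, `none` if no strategy was used. The item
wording of the original instrument is not public, so the default item set
is the standard WFP livelihood-coping battery (4 stress, 3 crisis, 3
emergency items); the tier map is configuration, and the classification
rule depends only on tiers, never on item identity.

## The Food Security Index

The CARI console has two domains: current status (food consumption) and
coping capacity (economic vulnerability plus livelihood coping). Each
indicator category maps to a 4-point score; for food consumption no
category maps to 2 (acceptable 1, borderline 3, poor 4), which is the CARI
convention and is also forced by the published cross-tabs (marginally food
secure households are essentially never borderline). The index is

\[
\mathrm{FSI} = \Big\lfloor \tfrac{1}{2}\Big( s_{\mathrm{FCS}} +
\tfrac{s_{\mathrm{PWFE}} + s_{\mathrm{CSI}}}{2} \Big) + \tfrac12 \Big\rfloor,
\]

i.e. the mean of the current-status score and the coping-capacity mean,
rounded to the nearest integer **with halves rounded up**. The rounding
mode is identifiable from the published terminal groups: acceptable FCS
with emergency coping and PWFE > 75% scores \((1 + 4)/2 = 2.5\) and is
reported as moderately food insecure, so banker's rounding (2.5 → 2) is
ruled out. `compute_fsi(rounding = "banker")` exists only to demonstrate
this sensitivity. Over the 48 category combinations the index is monotone:
worsening any single category never improves the classification (tested
exhaustively).

Percentages are reported the way the source tables print them: integers in
the console, one decimal in cross-tabs, both with half-up display rounding
(`round_half_up()`), matching SPSS-style output rather than R's default
half-to-even.

## Chi-square layer

`contingency_table()` / `crosstab()` wrap Pearson's \(X^2 = \sum (O-E)^2/E\)
without continuity correction (the r×c default of the software used for
the original analysis) via `stats::chisq.test()`, after dropping zero
margins; a margin with fewer than two observed categories is a degenerate
table (df = 0) and errors. Expected counts below 5 trigger a warning but
not a test switch — the plain chi-square is reported regardless, as in the
source analysis. The test suite checks the statistic against a brute-force
double-loop oracle to 1e-9 on random tables.

## CHAID segmentation

The segmentation target is the four-level FSI; predictors are the three
indicator categories, all declared ordinal in severity order, so merges
respect adjacency. `chaid_params()` defaults: merge and split level 0.05,
`max_depth = 3` (the published tree has exactly three predictor levels),
`min_parent = 100`, `min_child = 50`, Bonferroni on. The stopping sizes are
not published; these are the conventional defaults of CHAID software and
are fully exposed.

**Merge step.** `merge_categories()` is the classic Kass step: repeatedly
merge the adjacent pair of groups whose 2×J chi-square against the target
has the largest p-value, while that p-value exceeds `alpha_merge`.

**Split selection.** `best_split()` does *not* simply score the greedy
merge result. During development we found the greedy path is unreliable
precisely where it matters for auditability: on small nodes it can merge
the wrong pair first and then collapse a predictor whose optimal
merge-stable binary split is highly significant (in simulations with
3-category ordinal predictors, the greedy result differed from the optimum
in roughly 4–20% of random datasets depending on how optimality is scored).
Because the admissible search space is tiny for ordinal predictors with
3–4 categories (at most \(2^{c-1}-1\) partitions), `best_split()` instead
searches **exactly** over every admissible merged partition, where
admissible means: groups are contiguous in category order; the partition is
*merge-stable* — every adjacent pair of groups differs at `alpha_merge` by
the same 2×J test the merge step uses (Kass's stopping criterion imposed as
a constraint rather than reached greedily); and every prospective child has
at least `min_child` households. Each admissible partition is scored by its
Pearson p-value against the target, multiplied by two Bonferroni factors:

* the number of ways \(c\) ordered categories reduce to \(r\) groups,
  \(\binom{c-1}{r-1}\) (`bonferroni_multiplier()`; the nominal-scale
  Stirling-type count is implemented for completeness), and
* the number of candidate predictors at the node (`predictor_adjust`),
  so the split decision controls the familywise error of the whole split
  search — the variable-selection correction used by conditional-inference
  trees. Without it, three independent predictors each tested at 0.05
  yield a null split rate near \(1-(1-\alpha)^3 \approx 0.14\); with it the
  simulated rate is ≈ 0.04.

The smallest adjusted p wins if it is ≤ `alpha_split`; ties keep the
earlier predictor in the fixed order (FCS, CSI, PWFE), then fewer groups.
Candidates are compared on log-scale p-values (`pchisq(log.p = TRUE)`):
at survey scale the best splits have p-values far below double-precision
underflow, and comparing raw zeros would let the tie-break, not the
evidence, choose the partition.

`grow_tree()` applies this recursively; the tree is deterministic given
data and parameters and invariant to row order. Leaves partition the data
exactly; `terminal_groups()` reports each leaf's defining predicates, size,
modal FSI label, composition, and within-leaf PWFE distribution. On
calibrated synthetic surveys at the study's scale (n ≈ 1958 complete
households) the recovered structure is stable across seeds: food
consumption splits first, coping severity second in both the acceptable
and borderline branches, spending share third, and the poor-FCS branch
(~3.5% of households, below `min_parent`) is not segmented — ten terminal
groups in all. At larger n the poor branch legitimately exceeds
`min_parent` and may split further; that is a property of the stopping
rules, not a disagreement.

Limitations: merged groups are never re-split, missing predictor values
are not floated into groups (surveys are complete-cased first), and no
cross-validated risk pruning is applied — the tree is a descriptive
segmentation, not a predictive model.

## Synthetic-survey generator

The generator exists so the full pipeline is testable without the
restricted microdata. It is category-first with a latent severity level:

1. draw severity \(s\) from the mix (0.09, 0.69, 0.18, 0.04);
2. draw the (FCS, PWFE, CSI) category triple from per-severity
   conditional distributions, *conditioned on the triple mapping back to
   \(s\) under the index formula* (rejection sampling; acceptance
   probabilities 0.49–0.94 per level). The conditionals are transcribed
   from the published column-percent associations, zero cells kept exact.
   The conditioning step is deliberate: the real index is a deterministic
   function of the triple, so any coherent joint distribution must
   concentrate on index-consistent triples. Drawing the conditionals
   independently would place ~11% of mass on inconsistent triples and
   push the implied FSI marginal to 12.2/67.4/13.4/7.0 — enumeration over
   the 48 triples (`implied_marginals()`) shows this exactly — whereas the
   conditioned model reproduces the severity mix by construction while
   leaving the per-indicator conditionals close to their transcribed
   values;
3. synthesize raw fields that re-score to the drawn categories exactly:
   a random 0–7 day pattern nudged one day at a time into the FCS band
   (single steps of weight ≤ 4 cannot overshoot a band ≥ 14 wide), a
   spending pair whose ratio is drawn 0.004 away from band boundaries so
   2-decimal currency rounding cannot cross them, and coping answers whose
   maximum tier equals the drawn class;
4. demographics drawn independently of severity: female-headed share
   0.569, head age normal (48.7, 21.5) truncated to [18, 100] — the
   untruncated distribution would produce negative ages; truncation
   shifts the realized mean up ~2.5 years and shrinks the SD, which the
   package accepts as the cost of a coherent age support — civil-status
   mix (0.508, 0.234, 0.258), household-size bands (0.361, 0.594, 0.045)
   with sizes uniform within band, urban share 1023/2041;
5. each record independently becomes incomplete with probability 83/2041
   by blanking one randomly chosen indicator field.

What the generator does *not* emulate: the unpublished three-way joint
distribution beyond index consistency, any demographic–severity
correlation, spatial structure, currency dynamics, or item-level coping
patterns. Passing pipeline tests on synthetic data therefore demonstrates
the correctness of the scoring, testing and segmentation machinery and the
stability of the recovered tree structure under the published margins —
not the field realism of any particular joint behaviour.

## Problem sizes used by the test and acceptance runs

Marginal-recovery checks use n = 10,000 (two-point binomial tolerance);
pipeline calibration checks n = 5,000 (three-point tolerance on the FSI
row); tree-structure checks n = 5,000 and the study-scale n = 2,041;
oracle-equality checks 200 datasets of n ≤ 60 with 3-category predictors;
null-split simulations 100 replicates at n = 300. These sizes make every
stochastic assertion comfortably inside its tolerance while keeping a full
run in tens of seconds.
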