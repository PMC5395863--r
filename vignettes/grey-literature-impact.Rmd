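---
title: "Quantifying the impact of grey-literature studies on meta-analysis results"
author: "greymeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the impact of grey-literature studies on meta-analysis results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greymeta)
```

## The question and the procedure

Review teams routinely search for non-English reports, unpublished
studies and dissertations, yet these study types are rare among what
reviews finally include. `greymeta` operationalises the natural
sensitivity analysis: for every systematic review whose primary
meta-analysis includes at least one study of a given grey type, re-pool
the remaining studies *with the review's own summary measure, model and
pooling method*, and measure how far the pooled estimate moved. Reviews
with no study of the type are skipped, not errored — they are outside
the analysis set by construction (`run_impact()` returns `NULL`).

The unit of comparison is one review × one study type. One study may
carry several labels (a non-English dissertation counts in both
analyses); exclusions are one label at a time, never jointly.

## The pooling engine and its conventions

The engine exists so that a re-analysis can mirror whatever the
original review did. Its conventions are those of the software in which
the original Cochrane analyses were run, and several of them matter for
reproducing published numbers:

* **Continuity correction.** For RR/OR, 0.5 is added to *all four*
  cells of any 2×2 table containing a zero cell; double-zero-event
  tables are excluded on ratio scales (they carry no information about
  a ratio under this correction). Risk differences use the plain
  binomial variance; a table whose variance degenerates to zero (no
  events, or all events, in both arms) would otherwise be unpoolable
  under inverse-variance weighting, so its variance — and, for the
  double-zero case, its effect of 0 — is computed from the
  0.5-corrected cells. This is the one place the package departs from
  the textbook "usual variance", which is identically zero there.
* **SMD.** Hedges-corrected standardized mean difference,
  `g = J·d` with `J = 1 − 3/(4N − 9)`, variance
  `N/(n_t n_c) + g²/(2(N − 3.94))`. The correction can be switched off
  (`hedges = FALSE`) for Cohen's *d*.
* **Random effects.** DerSimonian–Laird only,
  `τ² = max(0, (Q − df)/C)`; other τ² estimators are deliberately out
  of scope. When a review's fixed-effect method is Mantel–Haenszel, its
  random-effects re-analysis still uses inverse-variance weights with
  DL τ² — the standard behaviour of review software, where MH weights
  exist only for the fixed-effect model.
* **Intervals.** 95% throughout with `z = 1.96` exactly (not
  `qnorm(0.975)`), matching the printed intervals the impact metrics
  are validated against. Pooling happens on the log scale for RR/OR and
  is exponentiated for reporting.
* **Degenerate input.** An empty (or all-non-estimable) study set pools
  to a *flagged* not-estimable result instead of raising. This is
  load-bearing: the "substantial" impact category is defined by the
  reduced analysis not existing.

The test suite checks the engine two independent ways: against
brute-force scalar-loop evaluations of the weight formulas on a
thousand random small instances (to 1e-10 relative error), and against
`metafor` (`rma`, `rma.mh`) as an external cross-check.

## Impact metrics: scales, rounding, edge cases

Percent changes are computed on the **natural** scale for every
measure, including ratio measures — that is the scale on which the
published with/without tables round-trip (e.g. a risk ratio moving
0.67 → 0.68 is a 1.5% change; its CI widths 0.39 → 0.40 give 2.6%).
Direction is ignored; only magnitudes are compared, so the metric is
invariant under a simultaneous sign flip of both estimates.

The published category scheme — negligible (<5%), small (5–10%),
moderate (11–20%), large (>20%) — leaves the interval (10, 11) unnamed.
`classify_change()` resolves this by rounding the percent change to the
nearest integer (half away from zero) before mapping; this reproduces
every printed category label, including a 10.1% change labelled
*small*. All reported rounding in the package is half-away-from-zero
(`round_half_away()`), estimates to two decimals, percentages to one;
internal computation is always full precision.

Two denominator edge cases are resolved conservatively: a zero
full-analysis point estimate (possible on difference scales) makes the
relative change non-estimable (`NA`), as does a zero full-analysis CI
width. A CI bound falling exactly on the null value counts as **not**
significant — the convention needed for an interval like (0.00, 0.04)
on a risk difference, or an SMD upper bound resting on 0, to be read as
a loss of significance.

## The reference results and their known inconsistencies

`grey_search_counts()` and `grey_impact_rows()` carry the published
corpus counts and the 32 published with/without re-analysis rows for
129 child-relevant Cochrane reviews (the underlying study-level data
are not redistributable; these printed pairs are the reproducible
surface). Recomputing every row from its own printed inputs shows the
source tables are not perfectly self-consistent, and the package
documents rather than hides this:

* three percent-change-in-point cells differ by one unit in the last
  decimal (printed 10.1/30.7/3.5 vs recomputed 10.2/30.6/3.4) — the
  source evidently computed from unrounded pooled estimates;
* the two CI-width-change cells of the probiotics review (printed 1.1
  and 3.5) are inconsistent with their own printed bounds (recomputed
  2.2 and 0.3) and cannot be explained by rounding;
* one row prints "-" where the reduced estimate is 0.00 although the
  change from 0.02 is computable (100%);
* three corpus-count percentage cells disagree with their own printed
  numerators and denominators.

The acceptance tests assert exact one-decimal agreement everywhere
else, and the documented deviation (not the printed value) on these
cells. All 28 printed category labels and both narrated significance
flips reproduce exactly.

## What the synthetic generator does and does not emulate

`generator_config()` defaults encode the corpus structure the package
is designed around:

| quantity | default | rationale |
|---|---|---|
| reviews per group | 57 / 38 / 34 | the three review groups' sizes |
| studies per review | `1 + NB(size 0.15, mu 50)` | median 3, IQR 1–35 |
| label prevalence | 4.4% / 1.9% / 1.9% | share of included studies |
| searched probability | 0.99 / 0.96 / 0.22 | share of reviews searching |
| per-arm sample size | lognormal, median 50, sdlog 1.3, floor 10 | participants per review median ≈ 600 |
| true effects | log RR ~ N(log 0.7, 0.15); MD ~ N(−0.5, 0.2) | typical intervention effects, away from the null so relative changes are well-scaled |
| between-study SD | 0.15 | mild heterogeneity on the analysis scale |
| grey effect shift | 0 | bias off by default |

Design choices worth knowing:

* **Labels only where searched.** Grey labels are assigned only within
  reviews whose search covered the type, with the within-searched rate
  rescaled (`p/searched_probability`) so the corpus-wide marginal
  prevalence still matches the configured value. This keeps the
  summary invariant `included ≤ searched` true by construction.
* **Arm data are generated from the effect, not alongside it.** A
  study's 2×2 table is drawn binomially from the effect-implied risks;
  continuous arms draw sample means and SDs from their sampling
  distributions. Generated data are therefore always internally
  consistent with the study-level effect.
* **The bias mechanism is one knob.** `grey_effect_shift` adds a
  constant to labelled studies' effects on the analysis scale; nothing
  else distinguishes grey studies. Simulation studies of language or
  publication bias should vary only this.
* **Independence assumptions.** Study size is independent of studies
  per review and of labels; the three labels are independent of each
  other; the publication-year distribution is only approximately
  matched (linearly increasing weights over 1990–2013). A real corpus
  has none of these independences exactly, and the extreme upper tail
  of participants per review (single reviews with millions of
  participants) is not reproduced. Passing simulation tests therefore
  demonstrates correctness of the pipeline's computations under a
  plausible corpus, not calibration to any real corpus beyond the
  medians and prevalences listed above.

## Simulation checks and problem sizes

Two statistical properties are checked end-to-end, at sizes chosen to
make the checks sharp but quick on a desk machine:

* With `between_study_sd = 0` and `grey_effect_shift = 0`, a 100-review
  corpus yields impacts that are overwhelmingly *negligible* (observed
  median |percent change| ≈ 0.3–0.4 across seeds) — removing an
  unbiased study moves a homogeneous pooled estimate only through
  sampling noise.
* With `grey_effect_shift = 1`, the with-estimate exceeds the
  without-estimate on the analysis scale on average; the directional
  effect is required to clear 3 standard errors across 20 seeded
  100-review replicates.

A corpus of 129 reviews generates and analyses in about a second, so
the defaults scale comfortably to larger simulation designs.

## Limitations

The package analyses what reviews *found and included*: it removes
grey studies that are present, which is not the same experiment as
adding grey studies that a search failed to locate. Heterogeneity
inference beyond DL τ² (Q-test p-values, I², prediction intervals),
Peto odds ratios, exact methods, meta-regression and joint multi-label
exclusion are out of scope. The impact categories are pragmatic
magnitude bands, not judgments of clinical significance.
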