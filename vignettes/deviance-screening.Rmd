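---
title: "Deviance scoring and pairwise MSD classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviance scoring and pairwise MSD classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devscreen)
```

## Overview

`devscreen` turns raw speech-battery measurements into ordinal deviance
scores against an age- and sex-matched neurotypical reference, and asks how
well those scores discriminate pairs of motor-speech-disorder subtypes.
This vignette documents the statistical procedure, the conventions chosen
where the published description of such batteries is silent, and what the
synthetic-data generator does and does not emulate.

## The normative reference

Each of the 15 measures is *oriented* so that lower always means more
deviant: measures whose pathological tail is high (articulation error
counts, jitter, shimmer, f0 SD of the sustained vowel) are negated before
any centile is computed. On the oriented scale, each stratum stores the
empirical centiles C1, C5 and C50 and the inter-centile distance
ICD = C50 − C5, which is the severity unit of the ladder. Orientation
before estimation guarantees C1 ≤ C5 ≤ C50 and ICD ≥ 0 by construction,
and makes the two tails exactly symmetric: building a high-tail reference
on values V equals building a low-tail reference on −V.

Conventions and tunables:

* **Centile estimator.** Linear interpolation between order statistics at
  fractional rank h = (n − 1)p + 1 (`stats::quantile` type 7). Any
  monotone estimator would serve; this one is the common software default
  and is pinned by an independent sort-and-interpolate oracle in the test
  suite.
* **Strata.** Sex crossed with half-open decade bands
  [20,30), ..., [70,80), [80,94) by default; the band definition is a
  configuration argument, since published batteries state only that
  matching is by age and sex. The final band is wider so speakers in their
  late eighties and nineties are not isolated in unstable strata.
* **MPT pooling.** Maximum phonation time is referenced by sex only. The
  measure shows no usable age effect in normative cohorts, and pooling
  widens the normal range rather than inventing age structure that is not
  there.
* **`min_stratum_n` (default 20).** The 5th centile of fewer than ~20
  observations is an extreme order statistic with very high variance;
  undersized strata are refused by name rather than silently tolerated.
* **Out-of-range ages.** Clamped to the nearest band with a warning rather
  than refused: clinical tables legitimately contain speakers just outside
  the normative range, and the nearest band is the least-wrong reference.

## The deviance ladder

With oriented value x, deficit D = C50 − x, the per-measure score is
evaluated **severe-first**: 4 if D > 2·ICD, else 3 if D > 1.5·ICD, else 2
if x < C1, else 1 if x < C5, else 0.

Three conventions deserve comment:

* **Reading of the severe bands.** The 1.5·ICD and 2·ICD thresholds are
  interpreted as bounds on the oriented deficit relative to the
  inter-centile distance (x ≥ C50 − 1.5·ICD keeps DevS ≤ 2). This reading
  makes the five bands contiguous and exhaustive for well-behaved strata.
* **Severe-first precedence.** In heavy-tailed strata C1 can lie *below*
  C50 − 1.5·ICD, making the "< C1" and "deficit" bands overlap. Evaluating
  severe bands first resolves the overlap deterministically in favour of
  the higher severity; a consequence is that for such strata level 2 may be
  unattainable (the ladder steps from 1 to 3). The test suite checks the
  ladder against an oracle that enumerates all band predicates and takes
  the maximum applicable severity — the two formulations agree everywhere.
* **Boundary inclusivity.** The normal range is x ≥ C5 inclusive; all lower
  band bounds are inclusive and upper bounds exclusive. Scoring is strictly
  one-sided: the non-pathological tail is never penalized.

**Degenerate references.** When ICD = 0 (a ceiling-effect stratum, e.g.
intelligibility where C50 = C5 = the maximum), the ladder has no severity
unit. We fall back to two thresholds — x ≥ C5 scores 0, C1 ≤ x < C5 scores
1, x < C1 scores 4 — and warn. This preserves the normal range and still
flags extreme deviance without dividing by zero.

**Composites.** The six voice and four DDK component scores are combined
by linear rescaling of the component sum to 0–6: 6·Σ/(4k). The published
accounts state only that the combination reaches a maximum of 6; linear
rescaling preserves component ordering, hits that maximum exactly when and
only when every component is 4, and is left unrounded because rounding
would discard information before classification. The DDK SMR−AMR
difference is scored like any other component, one-sided on its low tail.

## The classifier

A hand-written binary CART: exhaustive search over every feature and every
midpoint between consecutive distinct values, split quality measured by
weighted Gini impurity decrease, maximum root-to-leaf depth 3, minimum
leaf size 1, no pruning, no randomness. Depth 3 is deliberately shallow
for 10-per-group samples and is not tuned. Conventions: values equal to a
threshold go left; split ties break to the lowest feature index, then
lowest threshold; leaf-label ties break to the alphabetically earlier
group. These tie-breaks make fitting fully deterministic, which the test
suite asserts by refitting.

Validation is leave-one-speaker-out: n folds, the tree refit per fold with
identical hyperparameters, accuracies reported as percentages overall and
per class (for balanced 10/10 pairs the overall is exactly the per-class
mean). Feature importance is each feature's accumulated weighted Gini
decrease, normalized to sum to 1, reported from the tree fit on *all* pair
data — a single vector per pair mirrors how such analyses are usually
displayed — with fold-averaged importances written to a diagnostics file.
A split-free tree reports an all-zero vector rather than dividing by zero.
Summary rows aggregate accuracies as mean ± population SD (divisor n),
rounded half away from zero to one decimal.

An established CART implementation (`rpart`, matching hyperparameters)
serves as a cross-check oracle in the tests, never as the implementation;
agreement is asserted on training predictions across random datasets,
allowing for differing tie-breaks.

## The synthetic-data generator

The generator exists so every stage is testable without clinical data. It
emulates the *statistical structure the analysis assumes*, not real
speech:

* **Normative cohort.** 404 speakers by default, integer ages 20–93,
  allocated so every sex-by-band stratum holds at least `min_stratum_n`
  speakers. Raw measures are drawn per measure from log-normal
  distributions for strictly positive quantities (jitter, shimmer,
  repetition rates) and normal distributions otherwise, with small linear
  age and sex effects. The locations and scales are plausible for adult
  speakers but are simulation knobs, not normative claims.
* **Patient groups.** Six templates encode the qualitative subtype
  signatures (Kennedy: severe articulation with normal DDK; ALS and SCA:
  slow DDK; PD: voice-dominant with near-normal DDK; Wilson: articulation
  plus intelligibility; AoS: broad articulation/rate/DDK involvement).
  Templates are probability vectors over target levels 0–4 per dimension,
  applied per component for the composites. Raw values are placed by
  *inverse scoring*: uniformly inside the oriented centile band of the
  drawn level, so re-scoring recovers the level exactly. The unbounded
  level-4 band is capped at a 3·ICD deficit to keep values finite. When a
  drawn band is empty (the heavy-tail level-2 case, or a degenerate
  reference), the target moves to the nearest attainable more severe
  level, and the achieved level is recorded in the output so the
  round-trip contract stays exact.
* **What is deliberately not modelled.** Dimensions are drawn
  independently per speaker (an optional coupling between, say,
  articulation and intelligibility is plausible in real data but not
  quantified anywhere we could anchor it); the three AMR-CV items are
  emitted equal so the derived mean reproduces the placed rate exactly;
  the SMR−AMR difference follows by definition from the placed SMR and AMR
  rates rather than being independently targeted (the four DDK measures
  are linearly dependent, so only three are free); no audio, no perceptual
  severity ratings. Consequently, passing tests demonstrate the
  *machinery* — centiles, ladder, composites, trees, validation — not that
  any particular accuracy will be observed on real patients.

## Problem sizes and numerical choices in the test suite

The suite exercises the ladder against its enumeration oracle on 10,000
random references, the split search against exhaustive enumeration on
every node of 200 random fits of up to 25 samples, and the
generator-to-scorer round trip on 600 synthetic patients across all six
templates — sizes chosen to probe every band, tie and recursion depth
while keeping a full run around a minute. Statistical properties use
seeded replicate designs: two groups drawn from the *same* template hover
near chance under leave-one-speaker-out (mean accuracy within 35–65%
across 20 seeds — slightly below 50% is expected, because the held-out
speaker's class is always the training minority), while the
Kennedy-versus-ALS contrast, the strongest subtype separation, reaches at
least 90% accuracy in at least 8 of 10 seeds. Floating-point equality is
asserted exactly where arithmetic is exact (identities, determinism) and
at 1e−12 otherwise; split-gain comparisons in the fitter use a 1e−12
strict-improvement margin so tie-breaking is immune to rounding noise.

## Known limitations

* The composite combination rule and several ladder boundary conventions
  are package decisions where published descriptions are elliptical; they
  are documented above and pinned by tests, but other implementations may
  differ at exact band boundaries.
* Discrete age bands (not a continuous age model) follow the matching
  practice of normative batteries; speakers near band edges can change
  stratum with a birthday.
* The pairwise accuracies on synthetic data characterize the generator's
  templates, not any clinical population; per-pair averages must not be
  read as six-class classification performance.
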