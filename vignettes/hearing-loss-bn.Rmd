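---
title: "Modelling occupational hearing loss with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling occupational hearing loss with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearbn)
```

## The problem and the model

Noise-induced hearing loss is among the most common occupational diseases.
Screening programmes measure pure-tone air-conduction thresholds per ear and
condense them into a single legally meaningful quantity, the binaural
hearing-loss percentage. `hearbn` models how three personal factors —
gender, age and a family history of hearing problems — relate to that index
in a worker cohort, using a discrete Bayesian network so that any scenario
("a 52-year-old man with a family history") maps to an exact conditional
probability over severity groups.

### The loss indices

For one ear with thresholds $T_{500}, T_{1000}, T_{2000}, T_{3000}$ (dB HL),

$$\mathrm{monaural} = \left(\tfrac{1}{4}\sum_f T_f - 25\right) \times 1.5,$$

clamped to $[0, 100]$. The 25 dB HL term is the conventional low fence:
average thresholds at or below it count as no social handicap. The slope of
1.5 %/dB reaches total (100 %) loss at an average of about 91.7 dB HL. The
binaural index weights the better (smaller-loss) ear five-fold:

$$\mathrm{binaural} = \frac{5 \times \mathrm{better} + \mathrm{worse}}{6},$$

which is symmetric in the two ears, lies between the two monaural values,
and equals either when both ears agree — so no tie-breaking rule is needed.

Two clamping choices are deliberate. The floor at 0 is forced by the index's
definition as a percentage (an average threshold better than the fence is
"no loss", not negative loss). The cap at 100 follows the standard
social-hearing-handicap convention. Neither affects group discretization
boundaries, which sit well inside the range.

### Discretization

* **Loss groups I–V**: group I is *exactly* 0 %; groups II–V partition
  $(0, 100]$ with lower-exclusive/upper-inclusive cuts at 15, 30, 45 %.
  The two notations "I…V" and "Group 1…Group 5" are the same five states;
  I/O accepts both.
* **Age groups**: quintile bands `<29, 29–34, 35–39, 40–48, >=49` with
  lower-inclusive/upper-exclusive edges — note this is the *opposite* edge
  convention from the loss bands; both are stated explicitly because mixing
  them up moves boundary subjects between groups.
* **Family history**: No/Yes.

### The network

Variables: `gender` (Women/Men), `age_group` (5 states), `family_history`
(No/Yes), `loss_group` (5 states). The canonical structure
(`canonical_dag()`) makes the three predictors parentless and each a parent
of `loss_group`. This structure can express every conditional
$P(\mathrm{loss\ group} \mid \text{any subset of predictors})$, which is
exactly the space of published scenario tables; it uses
$1 + 4 + 1 + 4\times20 = 86$ free parameters, against $2\cdot5\cdot2\cdot5 -
1 = 99$ for the unfactorized joint.

Parameters are estimated per family as
$\hat p = (\text{count} + \alpha)/(\text{total} + \alpha\,k)$. The defaults
matter:

* `alpha = 0` (pure maximum likelihood) for headline fits and scenario
  tables — the reported probabilities are then exactly the observed
  conditional frequencies. A never-observed parent configuration falls back
  to a uniform row, a stated convention rather than an estimate.
* `alpha = 1` inside cross-validation, because the rarest severity group is
  genuinely sparse (on the order of a few cases per thousand workers) and
  unsmoothed fold fits would hand zero scores to held-out configurations.

Inference is exact sum–product variable elimination with a min-degree
elimination order; on four variables the order only affects speed, never
results. Probability arithmetic stays in linear space (the network is tiny);
only the BIC score works in log space. Evidence with zero marginal
probability raises an explicit "impossible evidence" error instead of
returning NaNs.

### Structure learning

`learn_structure()` is greedy hill climbing over single-edge additions,
deletions and reversals, scored by BIC
($\log L_{\mathrm{MLE}} - \tfrac{d}{2}\log N$, family-decomposable, cached
per family), with seeded random restarts and lexicographic tie-breaking so
results are reproducible bit for bit given the seed.

A consequence worth understanding before trusting any learned structure:
BIC is consistent but has a finite-sample detection threshold. Under the
default table-calibrated generating model, the family-history effect on the
loss group is about 1–2 percentage points, i.e. a mutual information of
roughly $1.6\times10^{-4}$ nats. At $n = 50{,}000$ the expected
log-likelihood gain of that edge (≈ 8 nats alone; large negative once the
other parents are present, because the edge then multiplies the CPT by ten)
cannot exceed its BIC penalty (≈ 22 / ≈ 216 nats), so the learner
*correctly* omits the edge at realistic sample sizes — for any seed. The
structure-recovery tests therefore separate two questions: (a) *can the
learner recover the canonical equivalence class when the signal is
identifiable?* — tested at $n = 50{,}000$ against a canonical-structure
network with interaction-rich, clearly detectable effects (synthetic by
construction); and (b) *does it behave correctly on table-calibrated data?*
— tested by confirming the gender and age adjacencies are found and the
sub-threshold family-history edge is not. Asserting full recovery from the
calibrated model would test the tables' effect sizes, not the algorithm.

## The synthetic-cohort generator

The real cohort behind the published tables is not deposited, so the
generator (`default_generating_model()`, `sample_cohort()`) emulates it from
what *is* printed:

* gender prior (0.1305, 0.8695), age-group prior (0.19, 0.20, 0.19, 0.21,
  0.21), family-history prior (0.8738, 0.1262) — the published marginals;
* $P(\mathrm{loss\ group} \mid \mathrm{fh}, \mathrm{gender},
  \mathrm{age})$ — the published 20-row three-factor conditional table, each
  row renormalized to sum exactly to 1 (printed rows sum to 100 ± 0.01 after
  rounding);
* integer ages uniform within the drawn band, bounded 17–66 (the cohort's
  observed range);
* with `audiograms = TRUE`, a loss percentage uniform on each group's
  interval (group I exactly 0, group V capped at the observed maximum of
  67 %) inverted into flat equal-ear thresholds ($T = 25 + \mathrm{pct}/1.5$),
  so indexing, discretization and generation round-trip exactly.

Two deliberate simplifications, and what they mean for the tests:

* **Predictors are sampled independently.** The real joint of gender × age ×
  family history is unpublished. This is harmless for every conditional
  recovery result — the estimate of $P(\mathrm{loss} \mid \mathrm{config})$
  converges to the generating row regardless of the predictor joint, which
  a dedicated test verifies by re-running recovery under a deliberately
  correlated predictor sampler — but it means synthetic *marginal* summaries
  (e.g. the overall loss distribution) need not match a real cohort's.
* **No noise-exposure covariates.** The generator reproduces the three
  studied factors only; passing tests demonstrate the machinery, not that
  these three factors suffice to describe real audiometric data.

## Validation machinery

Folds are a seeded random permutation cut into $k$ contiguous blocks (sizes
differ by at most one), unstratified — matching a plain disjoint-subsets
protocol. With five outcome groups and realistic prevalences, unstratified
folds can lack positives for rare groups; those (fold, group) AUCs are
reported as `NA` ("undefined"), never coerced to 0.5. The primary figure is
the pooled AUC over the joined out-of-fold predictions. The AUC itself is
the Mann–Whitney rank form with midrank tie correction, verified in the
tests against an all-pairs oracle to $10^{-12}$ and against an established
independent implementation.

## Numerical and interface conventions

* CPT rows must sum to 1 within $10^{-12}$; scenario rows are checked to
  $10^{-9}$ after mixing.
* Network JSON serialization writes probabilities as `%.17g` strings —
  plain JSON numbers at default precision do not round-trip IEEE doubles,
  and the serialization contract here is bit-exactness.
* All randomness flows through one explicit integer seed per entry point;
  the caller's RNG state is saved and restored, so library calls never
  perturb user scripts.
* Percentages are formatted to two decimals only at print time; all
  computation is full precision.

## Problem sizes used by the test suite

The suite exercises: exact-inference equivalence with brute-force
enumeration on random networks of up to 6 variables × 5 states; CPT
recovery at 200,000 samples and joint convergence at 500,000 (4-σ binomial
bands); single-factor conditional recovery at 500,000 records and per-cell
recovery at 100,000 (±0.3 percentage points); the cross-validation null at
20,000 records; and structure recovery at 50,000. These sizes were chosen so
that sampling error sits well inside each assertion's band while the whole
suite stays fast enough to run routinely.

## Known limitations

* Only the three published predictors are modelled; the published AUCs of
  the original study depend on its raw data and are not reproducible from
  summary tables, so the validation machinery is verified by construction
  (oracles, nulls, recovery) instead.
* The published baseline "initial percentage" row differs slightly from the
  raw empirical frequencies (89.04 vs 86.11 % for group I); the package
  reports model marginals and makes no attempt to force the two to agree.
* No missing-data estimation, continuous nodes, or causal interpretation:
  scenario tables are conditional probabilities, not intervention effects.
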