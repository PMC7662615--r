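# hearbn

Discrete Bayesian network modelling of occupational noise-induced hearing
loss.

Occupational health services routinely screen workers with pure-tone
audiometry and summarize the result as a "social" hearing-loss percentage —
an index with legal weight in disability assessment. `hearbn` implements the
full analysis chain used to study how gender, age and a family history of
hearing problems shape that index in a worker cohort:

1. **Audiometric indexing.** For each ear, the monaural loss percentage is
   computed from the air-conduction thresholds at 500, 1000, 2000 and
   3000 Hz:

   `monaural = (mean(T500, T1000, T2000, T3000) − 25) × 1.5`,

   clamped to [0, 100] (25 dB HL is the low fence). The binaural index
   weights the better ear five-fold:

   `binaural = (5 × better + worse) / 6`.

2. **Discretization.** The binaural index is banded into five groups
   (I: exactly 0 %; II: 0–15 %; III: 15–30 %; IV: 30–45 %; V: >45 %), age
   into five quintile bands (<29, 29–34, 35–39, 40–48, ≥49 years), and
   family history into No/Yes.

3. **Bayesian network.** A discrete network over
   {gender, age group, family history, loss group} factorizes the joint as
   `p(x1,…,xn) = ∏ p(xi | parents(xi))`. CPTs are estimated by (optionally
   Laplace-smoothed) maximum likelihood; structure is either the canonical
   star into `loss_group` or learned by BIC hill climbing with random
   restarts. Inference is exact (sum–product variable elimination), so any
   scenario question — "how likely is unimpaired hearing for a man of 50
   with a family history?" — is an exact conditional probability.

4. **Scenario tables and validation.** `scenario_table()` reproduces
   sensitivity tables (conditional loss-group distributions under every
   predictor configuration), and `cross_validated_auc()` scores the model as
   a per-group one-vs-rest probabilistic classifier with 10-fold
   cross-validation and rank-based (Mann–Whitney, tie-corrected) AUC.

Because the underlying 1418-worker dataset is not publicly deposited, the
package ships the study's published summary tables
(`inst/extdata/reference_cohort_tables.json`, accessible via `ref_tables()`)
and a seeded synthetic-cohort generator calibrated to them
(`default_generating_model()`, `sample_cohort()`), so every stage is testable
end to end.

## Worked example

```r
library(hearbn)

## audiometric indexing: left ear worse than right
audiogram_loss(c(30, 35, 40, 45, 20, 25, 25, 30))
#>   monaural_left monaural_right binaural
#> 1         18.75              0    3.125

## synthetic cohort calibrated to the published tables, canonical model
cohort <- sample_cohort(default_generating_model(), 10000, seed = 1)
fit <- hearing_bn(loss_group ~ gender + age_group + family_history, cohort)
fit
#> Discrete Bayesian network
#> Nodes: loss_group, gender, age_group, family_history
#> Edges: gender -> loss_group; age_group -> loss_group; family_history -> loss_group
#> Fitted to 10000 records (alpha = 0)
#> Free parameters: 86

scenario_table(fit, c("gender", "age_group"))
#> scenario table: P(loss_group | gender, age_group)
#> baseline (%): 88.55  10.34  1.07  0.05  0.00
#>  gender age_group     I    II  III   IV V
#>   Women       <29 98.25  1.75 0.00 0.00 0
#>   ...
#>     Men      >=49 73.36 22.23 4.31 0.10 0

cross_validated_auc(cohort, k = 10, alpha = 1, seed = 1)
#> 10-fold cross-validated one-vs-rest AUC (n = 10000, alpha = 1)
#> pooled (joined folds):
#>      I     II    III     IV      V
#> 0.6933 0.6759 0.8329 0.5686     NA
#> undefined per-fold AUCs (single-class test folds): IV:6 V:10
```

The scenario table reads directly as epidemiology: ~98 % of young women in
the synthetic cohort show no measurable loss, against ~73 % of men aged 49+,
and every row sums to 100 %. Undefined AUCs for the rarest groups are
flagged rather than silently reported as 0.5.

`run_pipeline(list(seed = 1))` wires the whole chain — simulate → index →
fit → scenarios → validate — and writes the cohort CSV, the fitted network
(JSON), all scenario tables and the AUC report, stamped with the seed and a
configuration hash.

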