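# psypatterns

Unsupervised discovery of preoperative psychological distress patterns from
item-level PHQ-9 and GAD-7 questionnaire responses, and covariate-adjusted
association analysis of those patterns against short- and long-term
surgery-related outcomes.

Fixed-cut-off screening (PHQ-9 ≥ 10 or GAD-7 ≥ 10) labels only a small
minority of surgical patients as distressed, yet subthreshold *combinations*
of symptoms predict worse outcomes. `psypatterns` is for biostatisticians and
perioperative researchers who want to subtype patients directly from the 16
item scores (each 0–3) instead of totals:

1. **Stage 1** — embed the 16 items (as z-scored patient vectors) with UMAP
   (`n_neighbors = 2`) and cluster them with HDBSCAN (`min_Pts = 2`) into
   symptom clusters.
2. **Reweight** — give each item weight `1/|its cluster|`, so every symptom
   cluster carries total weight 1.
3. **Stage 2** — embed patients from the reweighted scores
   (`n_neighbors = 30`) and cluster with HDBSCAN (`min_Pts = 95` at the
   reference cohort size of 11,376; scaled proportionally otherwise).
   Low-density patients stay noise (label −1); clusters below 200 (scaled)
   are merged into their nearest neighbour.
4. **Validate** — project an independent cohort through the fitted model and
   quantify profile consistency via an optimal pattern pairing (Pearson *r*
   over the 16 item means).
5. **Associate** — logistic models (odds ratios) for binary outcomes and
   linear models (slopes on a 0–10 scale) for continuous outcomes, adjusted
   for age, sex, education, BMI, Charlson comorbidity index, smoking,
   alcohol, surgery site and duration (plus anesthesia type for
   postoperative-discomfort outcomes), with the "normal psychological
   functioning" pattern as reference.

UMAP and HDBSCAN are implemented inside the package (Rcpp kernels for kNN,
layout optimisation and the mutual-reachability spanning tree), as are the
silhouette and Dunn validity indices, K-means/hierarchical baselines and
hyperparameter grid search. A calibrated synthetic-cohort generator (a
graded-response-style latent-class mixture over the 16 items, with planted
outcome effects and ground-truth labels) makes the whole pipeline testable
without access to patient data.

## Worked example

```r
library(psypatterns)
library(dplyr)

coh <- simulate_cohort(n = 2000, seed = 7)
fit <- run_discovery(coh$items)
fit
#> Two-stage pattern discovery
#>   patients: 2000  symptom clusters: 4  patterns: 6  noise: 30 (1.5%)
#>   1. normal psychological functioning                        n=674
#>   2. highly combined symptoms                                n=569
#>   3. nervousness and uncontrollable worry and excessive worry and fear n=266
#>   4. sleep disturbance and fatigue and eating disturbance and psychomotor change n=246
#>   5. sleep disturbance and fatigue and eating disturbance and psychomotor change and nervousness and uncontrollable worry and excessive worry and fear n=149
#>   6. trouble relaxing and restlessness and irritability      n=66
```

The four symptom clusters are the item groups discovered at stage 1; the six
patterns are patient subgroups, automatically named from the items their mean
profile elevates by ≥ 0.5 points over the cohort mean. The 30 noise patients
(1.5%) sat in no dense region and are excluded from the association models.

```r
tab <- assemble_analysis_table(coh, fit)
forest <- run_association_suite(tab)
forest |>
  filter(outcome == "any_complication", exposure_type == "pattern") |>
  select(exposure_level, estimate, ci_low, ci_high, p)
#> # A tibble: 5 × 5
#>   exposure_level                              estimate ci_low ci_high     p
#> 1 highly combined symptoms                       1.09   0.786    1.51 0.611
#> 2 nervousness and uncontrollable worry and …     1.13   0.749    1.69 0.569
#> 3 sleep disturbance and fatigue and eating …     0.970  0.627    1.50 0.893
#> 4 sleep disturbance and fatigue and eating … …   0.865  0.496    1.51 0.610
#> 5 trouble relaxing and restlessness and irr…     0.519  0.202    1.33 0.173
```

Each row is an adjusted odds ratio for any within-hospital complication,
comparing one distress pattern against the normal-functioning reference. At
n = 2,000 with the generator's modest default effects (true ORs around
1.1–1.3) the intervals are wide and straddle 1, as they should; the package's
recovery checks run at n = 20,000 where planted effects are recovered with
nominal interval coverage.

Plot helpers: `autoplot(fit)` (embedding scatter),
`plot_radar(export_radar(fit$profiles))` (per-pattern item profiles) and
`plot_forest(forest)`. `validate_cohort(fit, new_items)` applies a fitted
pipeline to an independent cohort; `tidy(fit)` and `glance(fit)` give
broom-style summaries.

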