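# ehrsubtype

Data-driven disease subtyping from longitudinal coded health records.

Patients who share a diagnosis often reach it along very different clinical
roads. `ehrsubtype` identifies such subtypes from the *prediagnostic* part of
coded electronic health records and then characterizes them clinically,
prognostically and genetically. It is aimed at biostatisticians and
epidemiologists who want a tested, reproducible reference implementation of
this kind of pipeline that runs end to end on synthetic cohorts, without
access-restricted population data.

## What it does

1. **Tokenization** — events are grouped into visits and rendered as token
   sequences with parallel age, calendar-year and visit streams
   (`build_vocabulary()`, `encode_cohort()`).
2. **Representation learning** — a small transformer encoder is trained with
   a masked-encounter objective and refined with a contrastive objective on
   temporally contiguous segment pairs; patients are embedded by
   concatenating mean-pooled first- and final-layer hidden states
   (`pretrain_masked()`, `contrastive_refine()`, `embed_patients()`).
3. **Subtyping** — K-means over K = 3..8 with the number of clusters chosen
   by prediction strength: the largest K whose cross-split pair-agreement
   statistic is at least 0.95,

   PS(K) = min over test clusters of the share of within-cluster pairs
   co-assigned by train-fitted centroids,

   plus silhouette, Davies–Bouldin, bootstrap ARI, consensus-clustering PAC
   and cross-source ARI as supporting stability metrics, and a per-patient
   confidence score `1 − d/d_max` (`select_k()`, `prediction_strength()`).
4. **Characterization** — per-cluster comorbidity prevalence with a 15%
   cross-cluster difference filter, weighted discriminative scores
   `WDS_k(c) = p_k(c)·(p_k(c) − mean_{j≠k} p_j(c))`, symptom trajectories
   over the ±5 years around diagnosis, cognitive-score trends with
   Mann–Whitney tests, prototype patients, and healthcare-utilization checks
   (Kruskal–Wallis, practice-level ICC).
5. **Prognosis** — five-year Kaplan–Meier curves, global and pairwise
   log-rank tests, and adjusted Cox models (Efron ties; age, sex, IMD,
   diagnosis year, visit frequency, 2-year Charlson index).
6. **Genetics** — polygenic-score contrasts (Welch t, BH-FDR, Cohen's d),
   SNP-dosage logistic regressions with Bonferroni correction, pairwise
   Fisher exact tests and carrier enrichment.

A synthetic-cohort generator (`cohort_config()`, `generate_cohort()`,
`generate_genetics()`, `split_by_practice()`) plants known subtype structure
— code signatures, visit rates, practice effects, symptom trends, survival
hazards, PRS shifts and SNP frequencies — so every stage has a recoverable
ground truth. See the vignette in `vignettes/subtyping-methods.Rmd` for the
models, assumptions and design decisions.

## Worked example

```r
library(ehrsubtype)

cfg    <- cohort_config(n_patients = 2000, seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic EHR cohort: 2000 patients, 261369 events (9817 post-diagnosis)
#>   practices: 50  planted subtypes: 5  vocab: 100 codes

fit <- ehr_subtype(cohort, seed = 42, B_bootstrap = 10, B_consensus = 20)
fit$report
#> Cluster-number selection by prediction strength
#>   PS by K: 3=0.654  4=0.927  5=0.984  6=0.912  7=0.546  8=0.751
#>   chosen K = 5 (threshold 0.95)
#>   silhouette 0.506 | Davies-Bouldin 0.766 | bootstrap ARI 0.996 | PAC 0.002

adjusted_rand(fit$labels, cohort$patients$true_subtype)
#> [1] 0.942

sdat <- survival_data(cohort, fit$labels)
lr   <- logrank(sdat$time, sdat$event, sdat$group)
round(lr$statistic, 1); signif(lr$p_value, 3)
#> [1] 193.6
#> [1] 9e-41
```

The fit takes under a minute on one CPU. Reading the output: K = 5 is the
largest cluster number whose prediction strength clears the 0.95 bar, so
five subtypes are selected — matching the five planted ones, as the
adjusted Rand index against the hidden labels (0.94) confirms, with a
bootstrap ARI of 0.996 and PAC near 0 indicating a stable solution. The
log-rank test then shows the recovered subtypes separate strongly on
five-year mortality, as planted through the per-subtype hazards.
`predict(fit, new_cohort)` maps held-out patients onto the fitted subtypes;
`prevalence_table()`, `wds_scores()`, `symptom_trajectory()`, `cox_fit()`,
`prs_pairwise()` and friends take the analysis from there.

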