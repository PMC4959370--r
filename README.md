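# progmod — paired prognostic expression modules from survival cohorts

`progmod` discovers **paired prognostic gene-expression modules** in a
cohort with genome-wide expression and time-to-event follow-up, and turns
each pair into a one-number risk score per patient. It targets the
reciprocal structure repeatedly seen in breast-tumour cohorts: a
co-expressed gene group that is *high* in poor-outcome patients,
anticorrelated with a second group that is *low* in those same patients.

The pipeline, in the field's standard notation:

1. **Quartile survival screen.** For every gene, the bottom and top
   expression quartiles of the cohort are compared by the unweighted
   log-rank test; the hazard ratio of high- vs low-expression patients is
   estimated by univariate Cox partial likelihood (Efron ties). With
   Benjamini–Hochberg adjustment across all genes, a gene is called
   high-risk (HR > 1) or low-risk (HR < 1) when adjusted p < 0.001 and the
   quartile medians are ≥ 2-fold separated.
2. **Clique clustering.** Each directional list becomes a graph connecting
   genes with Pearson r > 0.4; maximum cliques are extracted iteratively
   (exact search, remove-and-repeat), keeping up to two clusters per
   direction with > 15 genes each.
3. **Bi-clique pairing.** High and low clusters are paired through their
   anticorrelations (r ≤ −0.4): each pair contributes the maximal
   bi-clique with the most edges, giving up to four modules.
4. **Scoring.** A patient's module score is
   `median(high-risk genes) / median(low-risk genes)` (ratio on linear
   scale; the median difference on log2 scale). Patients are stratified at
   the score median (or quartiles) and strata compared by Kaplan–Meier
   curves, log-rank test, and hazard ratio.

A synthetic-cohort generator (`simulate_cohort()`) with planted
co-expression blocks, proportional-hazards survival, calibrated censoring
and activity-linked covariates makes the whole pipeline testable without
external data; `deg_screen()` adds the accompanying two-group
differential-expression analysis (e.g. TNBC vs non-TNBC).

## Worked example

```r
library(progmod)

sim <- simulate_cohort(sim_config(
  n_samples = 300, n_genes = 500,
  blocks = list(sim_block(15, "high_risk", 0.7),
                sim_block(15, "low_risk", 0.7)),
  cross_r = 0.5, beta = 1, censoring = 0.3), seed = 101)

fit <- progmod(sim$expr, sim$clinical, scale_hint = "log",
               min_cluster_size = 12)
fit
#> Prognostic module fit: 500 genes x 300 samples
#>   screen: 15 high-risk, 15 low-risk genes (adj p < 0.001)
#>   module 1: 14 high + 14 low genes, training log-rank p = 1.92e-14
```

The screen recovered the 15 + 15 planted genes; the bi-clique kept the 14
per side whose anticorrelations all clear the threshold, and the
median-dichotomised score separates training survival at p ≈ 2 × 10⁻¹⁴.
Validation on an independently simulated cohort from the same generative
model:

```r
held <- simulate_cohort(sim$truth$config, seed = 202)
validate_module(fit$modules[[1]], held$expr,
                held$clinical[c("sample", "time", "event")],
                mode = "difference")
#> Validation of module 1
#>   matched genes: 14/14 high, 14/14 low
#>   median stratification: low n=150, high n=150
#>   log-rank high vs low: chi-square = 71, p = 3.49e-17, HR = 3.26
```

High-scoring patients carry ≈ 3.3-fold hazard on held-out data. Scores
also track the generator's activity-linked clinical covariates:

```r
associate_scores(fit$scores[["module 1"]], sim$clinical, c("TNBC", "ER"))
#> TNBC: mann-whitney p = 6.22e-08 (nonTNBC n=242 med=-1.46; TNBC n=58 med=0.554)
#> ER: mann-whitney p = 7.32e-12 (pos n=231 med=-1.64; neg n=69 med=1.01)
```

`predict(fit, new_expr)` scores any cohort sharing gene identifiers;
`plot(fit)` draws the training Kaplan–Meier curves;
`write_modules_gmt()` / `write_results_json()` serialize modules and
screening tables. Real cohorts load through `read_expression()` (with
optional probe-to-gene median collapsing), `read_survival()`, and
`align_samples()`.

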