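---
title: "Discovering paired prognostic expression modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering paired prognostic expression modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progmod)
```

## The problem

Breast-tumour cohorts with expression profiling and follow-up show extremely
variable outcomes, and single-gene markers capture only part of that
variation. A recurring observation in such cohorts is a *reciprocal*
expression structure: a group of co-expressed genes (heavily enriched for
cell-cycle/proliferation genes) that is high in patients with poor outcome,
anticorrelated with a second co-expressed group (ER-signalling-like) that is
high in patients with good outcome. `progmod` implements a pipeline that
finds such paired structures directly from a training cohort and turns each
pair into a one-number prognostic score per patient.

## The procedure

`progmod()` runs four stages; each is also exported on its own.

**1. Genome-wide quartile screening** (`screen_all()`). For each gene,
patients are ranked by that gene's expression; the bottom and top
`fraction` (default 0.25) form the low- and high-expression groups. The
groups are compared with the standard unweighted log-rank test, and the
hazard ratio (HR) of the high- relative to the low-expression group is
estimated by a univariate Cox partial likelihood with Efron tie handling
(the simpler Pike observed/expected ratio is available via
`screen_control(hr_estimator = "pike")`). The log-rank p-values are
Benjamini–Hochberg adjusted *across all tested genes*, and a gene is
called:

* `HIGH_POOR` — HR > 1, adjusted p < 0.001, and the high group's median
  expression at least 2-fold the low group's;
* `LOW_POOR` — HR < 1 under the same significance and 2-fold separation
  criterion;
* `NONE` otherwise.

On the fold-change criterion: the two comparison groups are the extreme
quartiles *of the gene's own expression*, so the high group's median never
falls below the low group's — a per-direction ratio such as
"first/fourth > 2" cannot literally hold for a high-risk gene. The
criterion is therefore read as a *separation magnitude*: the two groups
must differ by at least the stated fold, in either direction, with the
direction of prognosis carried entirely by the HR. The literal per-direction
ratios remain available (`fold_mode = "literal"`) for transparency; in that
mode no high-risk gene can ever be selected, which is the point of keeping
it visible. Fold changes are formed on the linear scale; for log2 data
(`scale_hint = "log"`) values are exponentiated first, so the criterion
becomes a one-unit difference of median log2 expression.

Genes with constant expression, or with zero events in either extreme
group, are flagged and excluded from calling rather than imputed; flagged
genes keep `NA` statistics and do not enter the BH adjustment.

**2. Clique clustering** (`correlation_graph()`, `extract_cliques()`).
Within each directional gene list a graph connects gene pairs with Pearson
r strictly above 0.4 (computed over all samples). Clusters are extracted
iteratively: find a maximum clique (exact Bron–Kerbosch search via
`igraph::largest_cliques()`), keep it if it has at least `min_cluster_size`
genes (default 16, i.e. more than 15), delete its vertices, repeat. Only
the first `max_clusters` (default 2) clusters per direction are kept, so a
small number of coherent co-expression programmes survives rather than a
long tail of fragments. When several maximum cliques tie in size, the
lexicographically smallest gene-ID set is taken — this makes the whole
pipeline deterministic and independent of vertex ordering.

The size rule applies to the *pre-pairing clusters*; the bi-clique step
below can shrink a module side well under 16 genes, which is expected.

**3. Bi-clique pairing** (`pair_clusters()`). For every (high cluster, low
cluster) pair, a bipartite graph connects cross-pairs with Pearson
r ≤ −0.4 (the negative bound is inclusive). The module is the maximal
bi-clique with the greatest edge count |A|·|B| — i.e. the largest fully
anticorrelated sub-pair — found exactly by reducing bipartite bi-cliques to
maximal cliques of an auxiliary graph whose sides are made complete. Ties go
to the larger minimum side, then lexicographic order. With two clusters per
direction this yields up to four modules, relabelled `module 1`, `module 2`,
… by descending total gene count. A pair with no anticorrelation edge
yields no module.

**4. Scoring and stratification** (`module_score()`, `stratify()`). A
sample's module score is the median expression of the module's high-risk
genes divided by the median of its low-risk genes (ratio mode); the median
is taken per sample over genes, which is the only reading that produces a
per-patient score. For log-scale data the difference of the two medians is
the same quantity on the log scale, and is the default there because a
ratio of log-intensities is meaningless when values can be non-positive
(ratio mode refuses non-positive low-side medians and points the user to
difference mode). Ratio scores are invariant under global positive
rescaling of the matrix; difference scores under global additive shifts.
Median stratification labels samples strictly above the median score `high`
and the rest `low`; quartile stratification ranks the scores and labels the
top quarter `high`, bottom quarter `low`, middle `medium` (the top quarter
must be the poor-prognosis group for a score built high-over-low, even
though display conventions sometimes invert that wording). Rank-based
assignment with stable ordering makes ties deterministic.

**Validation and association.** `validate_module()` applies a fitted
module to a new cohort: module genes absent from the new platform are
dropped silently with a logged count (at least 3 matched genes per side
required by default, mirroring realistic cross-platform loss), samples are
scored and stratified, and the extreme strata are compared by log-rank test,
Cox HR, and per-stratum Kaplan–Meier curves. `associate_scores()`
summarises scores across levels of clinical covariates (ER, TNBC, grade,
TP53, subtype) with Kruskal–Wallis or Mann–Whitney omnibus tests and
BH-adjusted pairwise comparisons; nonparametric tests were chosen because
score distributions are ratio-shaped and often skewed. `deg_screen()`
provides the accompanying two-group differential-expression screen (Welch
t-test on log2 values, BH FDR, calls requiring |log2 FC| ≥ 0.5 with raw
p and FDR both < 0.05 — a fold-change *floor*, since a ceiling would
discard exactly the strongest signals), and `overlap_modules()` reports how
module genes intersect the calls.

## The synthetic cohort generator

Real discovery cohorts of this kind are consortium-scale downloads;
`simulate_cohort()` generates cohorts with the statistical structure the
pipeline assumes so that every stage can be exercised end to end.

One standard-normal latent activity $a_i$ per sample drives everything:

* a high-risk block gene is $\mu_g + \ell_c a_i + \ell_b u_i + \sigma
  \varepsilon$, a low-risk block gene the same with the sign of the signal
  flipped ($u_i$ is a block-specific factor, $\mu_g \sim U(6,10)$ emulating
  log2 intensities);
* survival is exponential with hazard $\lambda_0 e^{\beta a_i}$
  (proportional hazards in the latent activity, default $\beta = 1$ per SD,
  $\lambda_0 = 0.1$);
* censoring is an independent exponential whose rate is calibrated by
  numerical integration so the *expected* censoring fraction equals the
  target (default 0.3); ties between event and censoring resolve to the
  event;
* binary covariates follow logistic models in $a_i$ with base rates chosen
  once to resemble breast-cancer cohorts (ER-negative 0.22, TNBC 0.16,
  grade 3 0.48, TP53-mutant 0.30) and unit/0.8 slopes, so score–covariate
  associations are reproducible in silico. Note the *marginal* prevalence
  exceeds the base rate when the slope is nonzero.

The loadings are solved from the targets: with signal variance $v$ and
noise $\sigma^2$, the within-block correlation is $v/(v+\sigma^2)$, so
$v = \sigma^2 r_w/(1-r_w)$; the shared-factor share $\ell_c^2$ is set from
the cross-block target $r_x \le r_w$. With `cross_r = NULL` all signal is
shared and the closed form $r = \ell^2/(\ell^2+\sigma^2)$ holds exactly — a
property the tests verify empirically at n = 2000 within 0.03. With
`noise_sd = 0` block correlations are exactly ±1 (the degenerate limit used
by `fixture_small()`, a 16-gene × 24-sample deterministic fixture).

What the generator deliberately does **not** emulate: probe-level
measurement structure and platform mapping loss, batch effects, non-normal
marginal expression distributions, multiple independent latent programmes
with overlapping membership, non-proportional hazards, and informative
censoring. Passing tests on this generator therefore demonstrate that the
pipeline recovers the structure it is designed for, at realistic sizes and
noise — not that any particular clinical cohort contains such structure.

## Defaults and the parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `fraction` | 0.25 | extreme-group size: first vs fourth quartile |
| `adj_p_cutoff` | 0.001 | BH-adjusted log-rank threshold |
| `fc_high_cutoff` / `fc_low_cutoff` | 2 / 0.5 | fold separation of quartile medians |
| `pos_threshold` | 0.4 (exclusive) | Pearson r for co-expression edges |
| `neg_threshold` | 0.4 (inclusive) | Pearson −r for anticorrelation edges |
| `min_cluster_size` | 16 | genes per pre-pairing cluster |
| `max_clusters` | 2 | clusters per direction (up to 4 modules) |
| `min_matched` | 3 | matched genes per side in validation |
| DEG `lfc_cutoff` | 0.5 | |log2 FC| floor |

## Numerical choices and degenerate inputs

* Ties between event and censoring times: events first (standard risk-set
  convention, inherited from the `survival` package).
* Zero events overall: log-rank returns statistic 0, p = 1, flagged
  degenerate. Zero events in one group: HR is undefined and reported `NA`;
  such genes are excluded from selection rather than imputed.
* All tie-breaks (quartile cuts, clique choice, bi-clique choice, strata)
  are resolved by stable ordering or lexicographic gene IDs, so a fixed
  seed and configuration reproduce byte-identical GMT/JSON outputs.
* Probe collapsing uses the standard midpoint median for even probe
  counts; missing expression values are rejected at load unless the caller
  opts into dropping incomplete genes.
* Maximum-clique search is exact. The screened lists this pipeline
  produces are a few hundred genes with sparse-to-moderate graphs, well
  within exact-search range; pathological dense graphs are the caller's
  responsibility (the search is exponential in the worst case).

## Problem sizes used by the tests and acceptance script

The package's own checks run at sizes chosen to make the statistics
meaningful at interactive timescales: null calibration over 1000–2000 genes
at 250–300 samples; planted-module recovery at n = 400 samples and 2000
genes (two 20-gene blocks, within-block r ≈ 0.7, cross r ≈ −0.5, β = 1,
30 % censoring) across multiple seeds with independent held-out cohorts;
oracle equivalence of the survival statistics on dozens of ≤ 30-subject
fixtures against risk-table, product-limit and partial-likelihood
computations written from first principles; and clique/bi-clique
equivalence against exhaustive subset enumeration on graphs of ≤ 15 nodes.

## Known limitations

* The screen tests each gene at its expression extremes only; genes whose
  effect is monotone but weak across the middle of the distribution are
  penalised relative to a continuous-covariate Cox screen (a deliberate
  non-goal).
* Clusters are disjoint cliques; overlapping programmes and soft
  co-expression structure (WGCNA-style) are out of scope.
* Module scores weight all genes equally through the median; no
  gene-weighting or single-sample enrichment is attempted.
* The score's prognostic value on real data depends on platform matching;
  validation requires only 3 matched genes per side by default, and users
  should treat reports built on very few matched genes with caution.
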