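# triopgs

Between- and within-family factor models for psychiatric polygenic-score
(PGS) trios.

## What it is for

Polygenic scores for psychiatric disorders are correlated across people,
mirroring the pervasive comorbidity of the disorders themselves. But
population-level ("between-family") correlations mix genuine shared genetic
architecture with processes acting on parents: assortative mating,
gene–environment correlation, and selective participation in cohort
studies. In genotyped mother–father–child trios, Mendelian segregation
randomises the child's deviation from the midparent expectation, so the
"within-family" covariance of the same scores is immune to those processes.
`triopgs` is for researchers who want to compare the two and to quantify
the parent-level processes directly.

The package provides:

* **Synthetic trio generator** (`trio_config()`, `simulate_trios()`) — PGS
  panels with a known bifactor truth: general genetic p-factor +
  orthogonal subfactors, configurable cross-partner latent covariance
  (assortment), sex-specific latent mean shifts (participation selection),
  and Mendelian transmission (child = midparent + segregation deviation
  carrying half the population variance). A calibrated 11-trait structure
  (ADHD, ANOR, ASD, BIPO, MDD, NEUR, OCD, PTSD, SCHZ, ANXI, AUD) ships as
  the default truth (`pgs_loadings()`).
* **Trio SEM engine** (`trio_model_spec()`, `fit_trio_ml()`) — the
  model-implied 33-dimensional moment structure with meiosis-fixed 0.5
  transmission paths, full-information Gaussian ML on sufficient
  statistics, analytic gradients, observed-information standard errors and
  BIC.
* **EFA + rotation** (`extract_efa()`, `geomin_rotate()`,
  `bifactor_geomin_rotate()`, `sequential_efa_search()`) — ML factor
  extraction, gradient-projection geomin and bi-factor geomin rotation,
  and the stepwise between/within dimensionality-and-equality search
  scored by BIC.
* **Confirmatory pipeline** (`fit_cfa_assortment()`,
  `fit_cfa_selection_means()`, `partner_pgs_correlations()`,
  `build_report()`) — partner latent correlations with the within-family
  variance fixed to 1, sex-specific latent means with the within-family
  mean fixed to 0, descriptive partner score correlations, and a
  serialisable report.

The core model: stacked trio observations follow
`Sigma = (I3 ⊗ Λ) Ω (I3 ⊗ Λ)' + U ⊗ Θ`, where `Ω` is the latent couple +
child covariance implied by `F_child = 0.5 F_mother + 0.5 F_father + S`,
`Var(S)` fixed by design (half the population variance under random
mating), `Λ` the bifactor loading matrix shared by all family members and
`Θ` the residual (unique genetic) variances, transmitted with the same 0.5
rule. Fixing the within-family variance (and mean) identifies the
between-family factor variances `ψ`, partner covariances `γ` and parental
latent means `α`; partner correlations are reported as `γ/ψ` and selection
means in latent SD units `α/√ψ`.

## Worked example

Generate a panel with assortment on the constraint subfactor and a
father-specific selection shift, then estimate both:

```r
library(triopgs)

cfg <- trio_config(
  partner_cross_cov      = c(0, 0, 0, 0.257),  # P, NDV, PSYCH, CONS
  selection_means_father = c(0, 0, 0, 0.183),
  n_trios = 25293, seed = 11)
trios <- simulate_trios(cfg)

assort <- fit_cfa_assortment(trios)
partner_latent_correlations(assort)
#> # A tibble: 4 x 5
#>   factor estimate std.error conf.low conf.high
#>   <chr>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 P      -0.0225    0.00917  -0.0404  -0.00447
#> 2 NDV    -0.0129    0.0139   -0.0402   0.0143
#> 3 PSYCH   0.00641   0.0191   -0.0311   0.0439
#> 4 CONS    0.219     0.0799    0.0627   0.376

sel <- fit_cfa_selection_means(trios)
dplyr::filter(latent_selection_means(sel), factor == "CONS")
#> # A tibble: 2 x 6
#>   parent factor estimate std.error conf.low conf.high
#>   <chr>  <chr>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 mother CONS     0.0326    0.0231  -0.0126    0.0779
#> 2 father CONS     0.158     0.0248   0.109     0.207
```

The constraint partner correlation (truth 0.257) is recovered at 0.219
with a 95% interval [0.063, 0.376], and the father-only selection shift
(truth 0.183) at 0.158 [0.109, 0.207] while the mother estimate covers
zero — single-replicate sampling noise at this n, not bias; the replicate
studies in `tests/testthat/test-acceptance.R` average 20 such panels.

The exploratory stage on the same data:

```r
led <- sequential_efa_search(trios)
attr(led, "best_model")      # row index of the BIC-best model
#> [1] 13
tibble::as_tibble(led)[attr(led, "best_model"), c("model", "bic")]
#> # A tibble: 1 x 2
#>   model                          bic
#>   <chr>                        <dbl>
#> 1 4 factors, equal structure 1549301.
```

With the four-factor "bold" generating structure, the search settles on
four equal-structure factors at both levels; generating from the full
five-factor structure (`pgs_loadings("full")`) moves the winner to five.
`autoplot(led)` draws the BIC path, `autoplot()` on a rotation solution a
loading heatmap, and `plot_selection_means()` the sex-specific mean chart.

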