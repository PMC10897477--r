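---
title: "Between- and within-family factor models for psychiatric polygenic score trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between- and within-family factor models for psychiatric polygenic score trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopgs)
library(dplyr)
```

## The problem

Psychiatric disorders are heavily comorbid, and polygenic scores (PGS) for
different disorders are correlated across people. Population ("between
family") correlations among PGS, however, confound the genetic architecture
of comorbidity with three processes that act on *parents*: assortative
mating (partners resemble each other genetically), gene–environment
correlation, and selective participation in cohort studies. Mendelian
segregation provides a built-in randomisation: conditional on the parental
genotypes, the child's deviation from the midparent expectation is
randomly assigned. Comparing the factor structure of a PGS panel computed
between families (child scores) and within families (child scores with the
parental scores regressed out) therefore separates genuine shared genetic
architecture from parent-driven artefacts.

`triopgs` implements this comparison end to end for complete
mother–father–child trios measured on a panel of 11 psychiatric PGS
(ADHD, ANOR, ASD, BIPO, MDD, NEUR, OCD, PTSD, SCHZ, ANXI, AUD):

1. a synthetic trio generator with known latent truth,
2. a trio structural-equation engine (Gaussian full-information ML),
3. ML factor extraction with geomin / bi-factor geomin rotation,
4. a sequential between/within factor search scored by BIC, and
5. confirmatory models for partner latent correlations (assortment) and
   sex-specific latent means (participation selection).

## The trio model

For each trio, stack the mother, father and child score vectors into a
33-dimensional observation. The measurement model is a bifactor structure:
a general genetic factor (the "p-factor") loading on all 11 scores and a
small number of orthogonal subfactors loading on subsets, with loading
matrix $\Lambda$ (shared by all three family members), intercepts $\nu$,
scalings $\delta$ and residual variances $\varepsilon$. Latent factors obey
Mendelian transmission with *fixed* paths:

$$F_{child} = 0.5\,F_{mother} + 0.5\,F_{father} + S,$$

where the segregation deviation $S$ is independent of the parents. Under
random mating the segregation variance is half the population factor
variance; fixing it (to 0.5 in the population metric) anchors the latent
scale, and fixing the within-family latent mean to zero anchors the latent
origin. Everything else — between-family factor variances $\psi$,
mother–father latent covariances $\gamma$ (assortment), parental latent
means $\alpha_m, \alpha_f$ (selection), loadings and residuals — can be
estimated by maximising the multivariate Gaussian likelihood of the stacked
vector. Because the likelihood depends on the data only through the sample
mean and covariance, fits cost the same at 2,000 and 200,000 trios.

Trait-specific residual variance in a PGS panel is itself genetic, so by
default the generator and the model transmit the unique components with the
same 0.5/0.5 + segregation rule (`transmit_uniques = TRUE`), which keeps
`Var(child) == Var(parent)` and adds $0.5\,\varepsilon$ to the parent–child
cross-covariances. A switch disables this in both places for sensitivity
analysis, since published trio analyses do not pin this choice down.

### Identification and parameterisation

* Transmission paths are never free; they are 0.5 by meiosis.
* Mother and father measurement parameters are tied equal (one loading
  matrix, as in published applications); intercepts are fixed at 0 and
  scalings at 1 for standardized scores, though both slots exist in the
  moment algebra for non-standardized data.
* Variances are optimised on the log scale and factor covariances only
  through per-factor partner covariances, so Heywood-style crashes cannot
  occur mid-optimisation; a numerically singular implied covariance yields
  a finite penalty rather than `NaN`.
* Local identification is verified before fitting from the rank of the
  Jacobian of the implied moments. The check is evaluated at a
  deterministic perturbation of the start because special points can be
  degenerate: with a two-indicator subfactor, zero partner covariance and
  within-family variance exactly half the between variance, the ratio of
  the two loadings is locally flat. The same geometry can make the
  observed information nearly singular at the optimum, in which case
  standard errors are computed from a pseudo-inverse and the affected
  loading contrasts should not be interpreted (the derived quantities
  reported by the pipeline — partner correlations and standardized latent
  means — do not load on those directions).

### The two confirmatory models

*Assortment.* Following the convention of fixing the within-family latent
variance to 1, the partner covariance $\gamma_j$ of factor $j$ is free and
the reported quantity is the standardized covariance
$b_j = \gamma_j/\psi_j$, a partner correlation. Wald intervals come from
the observed information via the delta method. All factors' partner
covariances are estimated jointly by default; `fit_cfa_assortment(factors =)`
fits them factor-by-factor instead, since either convention is defensible
and the two agree closely in practice.

*Selection.* With the within-family mean fixed at zero and scores *not*
re-centered per sex, the parental latent means are identified; deviations
from zero measure how the participating mothers/fathers differ from the
population implied by the within-family anchor. Estimates are reported in
latent SD units ($\alpha/\sqrt{\psi}$). Per-sex centering would remove the
signal entirely, so `fit_cfa_selection_means()` refuses data whose parent
blocks are each exactly mean-centered; `standardize_panel()` likewise only
offers pooled reference groups (parents, children, or everyone — the
default is the parent generation pooled across sexes; the choice is a
convention, and it is configurable because published pipelines do not state
it).

## Exploratory stage

The between-family layer is the covariance of the child scores; the
within-family layer is the covariance of the child-minus-midparent
deviations, multiplied by 2 to return to the population metric (the
deviation carries exactly half the population variance under the fixed
paths). The sequential search adds one factor between families, then one
within families, then constrains the new factors' loadings to be equal
across layers, scoring every step with
$\mathrm{BIC} = q\log n - 2\ell$. Using the cheap two-layer covariance
representation for the exploratory stage and the exact trio likelihood for
the confirmatory stage keeps the search fast while preserving the
identification logic; the equality constraint is on the loading matrix,
with layer-specific residual variances.

ML extraction is by profile likelihood over the uniquenesses (canonical
eigenvalue form with analytic gradient), bounded below at `1e-4`; a
solution pinned at the bound is flagged as a Heywood case. The stepwise
ledger records such events rather than warning at every overfitted step.

Rotation is by gradient projection. Plain geomin is oblique with the
criterion
$f(\Lambda)=\sum_i\big(\prod_j(\lambda_{ij}^2+\epsilon)\big)^{1/k}$;
bi-factor geomin is orthogonal and applies the criterion to all columns
except the first, so the general factor absorbs the shared variance while
the subfactors are driven to simple structure — matching a model with one
general factor and uncorrelated subfactors. Defaults: $\epsilon = 0.01$
(the usual convention at this panel size) and 30 random starts, because
geomin criteria have local minima; step-halving guarantees monotone
descent, and every converged solution reproduces the unrotated common
variance to numerical precision. Rotated solutions are only defined up to
column permutation and sign; `align_loadings()` matches a solution to a
reference by absolute congruence (exhaustive over permutations for
$k \le 6$) and is used for all recovery comparisons.

## The synthetic generator

`trio_config()` + `simulate_trios()` generate trio panels whose population
moments are known exactly:

* couples are drawn jointly from a $2k$-dimensional Gaussian with marginal
  factor covariance $\Psi$, cross-partner covariance $\Gamma$ and means
  $(\alpha_m, \alpha_f)$;
* children are midparent + segregation as above;
* observed scores are $\Lambda F + u$.

The packaged default truth is the calibrated 11-trait bifactor structure:
`pgs_loadings("bold")` (general + neurodevelopmental + psychotic +
constraint simple structure, residual variances completing unit score
variance) for confirmatory work, and `pgs_loadings("full")` (all five
rotated factors including the residual factor that is almost entirely MDD
error, with the published residual variances) for exploratory work.
Selection is modelled as latent mean shifts of the participating parents —
the quantity the confirmatory model estimates. A threshold-participation
mode (retain couples whose liability index exceeds a population quantile)
is included as a robustness check because real participation is closer to
truncation than to a mean shift; truncation also shrinks latent variances,
which the mean-shift model does not emulate.

What the generator does *not* emulate: genotypes, linkage disequilibrium
and PGS construction error (simulation is at the score level);
non-Gaussian score distributions; dynastic/indirect genetic effects;
gene–environment correlation as a distinct mechanism (its trio-level
footprint overlaps with the selection shifts); relatedness beyond a single
trio; missing data (complete trios only). Passing recovery tests therefore
demonstrates that the estimators invert the stated generative mechanism at
scale, not that every real-data complication is handled.

## Numerical choices

* L-BFGS-B with analytic likelihood gradients, `maxit = 2000`,
  `factr = 1e7`; 10 jittered multi-starts by default (`n_starts`), since
  the trio likelihood can have local optima. Replicate studies that only
  need point estimates can set `n_starts = 1` and `se = FALSE`; at
  25,293 trios the deterministic pattern-based start converges reliably.
* EFA extraction: `factr = 0.01` with one restart from the solution, which
  recovers an exact population structure to `1e-6` in the common variance.
* Rotation: gradient-projection tolerance `1e-9` on the projected
  gradient, 1,000 iterations, 20 step-halvings.
* Ties and degenerate inputs: zero-variance traits, collinear parental
  scores, factors with no indicators, and non-PSD couple covariances are
  rejected with errors naming the offending trait/factor/block.

## Scale of the shipped checks

The packaged tests run the full recovery study at the study scale
(25,293 trios, 20 replicate seeds per target) for the confirmatory and
rotation stages, and scaled-down majority-vote checks (4,000 trios,
5 seeds) for dimensionality recovery of small structures; property tests
(symmetry, positive semi-definiteness, fit preservation, gradient
correctness) run on hundreds to a thousand random draws. One
simulate-and-fit cycle at the study scale takes a few seconds.

## Known limitations

* Factor covariances are diagonal per layer (orthogonal bifactor); oblique
  confirmatory structures are out of scope.
* No FIML for incomplete trios; trios with any missing score are excluded
  by design.
* EFA-stage loading standard errors are not computed (the confirmatory
  stage provides SEs); BIC comparisons use raw differences, not weights.
* Wald intervals can be poor for partner correlations of weakly measured
  subfactors (few, small loadings) at moderate n, where the profile
  likelihood is skewed.
* The sequential search explores the verbal step grammar (between, within,
  equal) exactly; other orderings of the same model space could in
  principle select differently at knife-edge BIC margins.
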