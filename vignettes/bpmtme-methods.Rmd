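---
title: "Methods: the Poisson-lognormal multi-trait multi-environment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Poisson-lognormal multi-trait multi-environment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmtme)
```

## The model

Count phenotypes (infected spikelets, panicle numbers, seed counts) measured
on several traits across several environments are overdispersed and
correlated.  `bpmtme` fits the Bayesian Poisson-lognormal multi-trait
multi-environment model (BPMTME): conditional on the random effects, the
count of trait $l$ for line $j$ in environment $i$, unit $k$, is

$$Y_{ijk}(l) \sim \mathrm{Poisson}\!\left(\exp\{\eta_{ijk}(l)\}\right),
\qquad
\eta_{ijk}(l) = \beta_i(l) + b_{1,j}(l) + b_{2,ij}(l) + c_{ijk}(l),$$

with environment-by-trait intercepts $\beta$, line main effects
$b_1 \sim N(0,\, G \otimes \Sigma_t)$, line-by-environment interactions
$b_2 \sim N(0,\, \Sigma_E \otimes G \otimes \Sigma_t)$, and an
observation-level disturbance $c_{ijk} \sim N(0, \Sigma_c)$ whose
exponential makes the marginal distribution Poisson-lognormal, absorbing
overdispersion and residual cross-trait correlation.  $G$ is the genomic
relationship matrix among lines ($J \times J$), $\Sigma_t$ and $\Sigma_c$
are $L \times L$ trait covariances and $\Sigma_E$ is the $I \times I$
environment covariance.  The univariate special case with $L = 1$ (BPME)
runs through the identical code path, with $\Sigma_t$ and $\Sigma_c$
degenerating to scalar variances.

## Augmentation and the exact Gibbs sampler

The Poisson likelihood is approximated by a negative binomial with a large,
fixed size parameter $r$ (default 1000, never estimated): a Poisson($\mu$)
pmf and an NB with mean $\mu$ and size 1000 differ by less than 0.01 in
total variation for $\mu \le 10$ (asserted in the test suite).  Writing
$\eta^* = \eta - \log r$ puts the NB kernel in logit form, and Polya-Gamma
augmentation of each observation,
$\omega_{ij}(l) \mid \cdot \sim \mathrm{PG}(y_{ij}(l) + r,\ \eta^*_{ij}(l))$,
renders every location block conditionally Gaussian:

$$\log P(Y \mid \cdot) \;\propto\; y^{*T}\eta^* - \tfrac12\,
\eta^{*T} D\, \eta^*, \qquad y^* = \tfrac{y - r}{2},\ D = \mathrm{diag}(\omega).$$

Covariances carry the Huang-Wand hierarchy: inverse-Wishart priors with
inverse-gamma auxiliary scales ($\nu = 2$, bound $A = 10^4$ by default),
giving marginal half-$t$ priors on each standard deviation.  All full
conditionals are then exact draws (normal, inverse-Wishart, inverse-gamma,
Polya-Gamma), applied in the fixed order $\beta^*$, $b_1$, $b_2$, $c$,
$\Sigma_t$, $a_t$, $\Sigma_E$, $a_E$, $\omega$, $\Sigma_c$, $a_c$.

Two structural conventions are load-bearing and enforced package-wide:
observations are stacked environment-major, then line, then unit, with trait
innermost; and effect vectors follow the Kronecker orders $G \otimes
\Sigma_t$ (line outer, trait inner) and $\Sigma_E \otimes G \otimes \Sigma_t$
(environment outer, line middle, trait inner).

### Derivation checks rather than trust

The conditional updates were derived by conjugacy and are *validated*, not
assumed, by two independent instruments in the test suite:

1. **Grid proportionality.** Every tractable full conditional, evaluated
   from its returned parameters, must differ from an independently coded
   dense joint log posterior by a constant over a grid of block values
   (agreement to $10^{-8}$).  The $\omega$ conditional is excluded: the
   Polya-Gamma density has no closed form (density evaluation is outside
   this package's scope), and the same intractable factor cancels from the
   joint; $\omega$ is covered by the moment oracles and by (2).
2. **Successive-conditional simulation.** On an $I=2$, $J=3$, $L=2$ model,
   forward draws from the prior-plus-data-model and a chain alternating
   Gibbs sweeps with data refreshes must have identical marginals; 22 scalar
   functionals are compared by ESS-adjusted $z$-scores at the 0.001 level.
   One subtlety: the refresh must redraw $Y$ *and* $\omega$ jointly (first
   $Y$ from the size-$r$ NB, then $\omega \sim \mathrm{PG}(y + r, \eta^*)$),
   because the augmented joint's PG factor depends on $y$, so $Y$'s full
   conditional given $\omega$ is not the marginal NB.  This test is sharp:
   it detects the non-invariant $Y$-only refresh as a divergence within a
   few dozen sweeps.
   This check uses light-tailed hyperparameters ($\nu = 30$, $A = 0.3$,
   small intercept variance) — valid for any proper setting, and necessary
   because the default half-$t$ scale priors put non-negligible forward mass
   on predictors whose NB counts overflow.

## Sampling Polya-Gamma variates at large shape

The sampler needs $\mathrm{PG}(b, d)$ draws with $b = y + r \ge 1000$.  We
draw the leading terms of the infinite gamma convolution
$\omega = (2\pi^2)^{-1}\sum_k g_k /\{(k - \tfrac12)^2 + d^2/(4\pi^2)\}$,
$g_k \sim Ga(b, 1)$, exactly, and replace the remainder by a single gamma
variate matched to the exact tail mean and variance (closed forms exist for
both).  The number of exact terms adapts to the shape as
$\lceil 200/\sqrt{b}\rceil$ (at least 6, at most `trunc` = 200): each
retained term is within $O(b^{-1/2})$ of Gaussian, so the moment-matched
tail absorbs the truncated mass with error far below Monte Carlo noise
precisely where few terms are kept, while small shapes retain the full
200-term depth.  Validation: closed-form mean/variance oracles at shapes 1
through $10^4$, additivity in $b$, tilt symmetry, and the
successive-conditional test above (which exercises the sampler inside the
full model).  This schedule is what makes desk-scale runs practical: the
$\omega$ refresh dominates the per-iteration cost.

## Numerical choices

* **Location draws** use precision-Cholesky sampling.  With a diagonal $G$
  (the simulation scenarios use $G = I$), the $b_1$ and $b_2$ conditionals
  factor into $J$ independent systems of size $L$ and $I L$; a dense $G$
  falls back to full $JL$- and $IJL$-dimensional solves.
* **Inverse-Wishart draws** use the Bartlett decomposition of the inverted
  scale matrix; validity requires degrees of freedom exceeding the dimension
  minus one, guaranteed by the conjugate updates.
* **Initialization**: $\beta^*$ from log mean counts per environment-trait
  (floored at $10^{-3}$ to tolerate all-zero cells, with a warning, since
  structural zeros sit outside the Poisson-lognormal assumption);
  covariances at $0.1 I$; auxiliaries at 1; random effects at 0; $\omega$
  from one refresh.  An overdispersion-safe, feasible start.
* **Relationship matrices** get an escalating diagonal jitter (relative
  $10^{-8}$, growing tenfold up to $10^{-4}$) until the Cholesky succeeds,
  because $G^{-1}$ enters the Kronecker precisions.
* **Prior-scale reading**: the intercept prior is weakly informative with
  covariance $10^4 I$.  The literal reading of the source specification
  (covariance $10^{-4} I$, a tight prior) contradicts its stated intent but
  is available as `literal_sigma_v = TRUE`.
* **Replicates** are collapsed by raw summation with *no* log-$K$ offset;
  intercepts absorb the scale, so fitted $\beta$ equals the per-replicate
  $\beta$ plus $\log K$.  Recovery comparisons subtract that offset.
* Indexing is 1-based internally (R idiom); the stacking order is the
  convention stated above.

## What the simulator emulates — and what it does not

`scenario_params()` returns the two study scenarios verbatim: $I = 3$
environments, $L = 2$ traits, $J = 200$ genotypes, $K = 5$ replications,
$G = I_{200}$, intercepts $(0.20, 0.25, 0.15, 0.20, 0.30, 0.32)$, and the
printed $\Sigma_t$, $\Sigma_E$, $\Sigma_c$ (S1: generating trait correlation
0.8; S2: 0.3).  `simulate_dataset()` draws effects at those constants and
counts per replicate, which are then summed for analysis — mirroring the
study pipeline.  The generator is validated by moment recovery (empirical
covariance of generated $b_1$ and $b_2$ against $\Sigma_t$ and the Kronecker
structure), Poisson-mean limits, and overdispersion/monotonicity properties.

Two honest caveats follow directly from those constants.  First, the printed
covariances put very little signal into the predictor: the per-cell standard
deviation of $\eta$ beyond the intercept is about 0.07, against Poisson
noise with coefficient of variation about 0.4 on collapsed sums near 6.  An
oracle that knows the true rates reaches a Spearman correlation of only
about 0.2 against observed counts per trait-environment cell, which bounds
any masked-cell cross-validation accuracy from above; published accuracies
in the 0.5-0.7 range are not reachable under these constants with
masked-cell evaluation, and the package reports what the faithful
computation produces rather than tuning toward the published table.  Second,
real count data carry features the generator does not emulate — zero
inflation (explicitly outside the model), marker-derived non-identity $G$,
unbalanced replication — so passing simulation tests demonstrates correct
inference under the stated model, not field performance.

## Cross-validation and accuracy

`make_cv1_partitions()` implements CV1: whole (environment, line) cells are
masked jointly for all traits, never leaving a line unobserved everywhere.
Cell-level masking of a fraction of cells is the default; `by_line = TRUE`
instead selects a fraction of lines and masks each in a random proper subset
of its environments.  Masked cells are removed from the training likelihood
entirely (a leakage test asserts bit-identical chains when masked counts are
perturbed).  Predictions for masked cells average
$r \exp(\hat\beta^* + \hat b_1 + \hat b_2)$ over retained samples with the
unobserved $c$ at its prior mean of zero — drawing $c$ would only add rank
noise to a point prediction.  Accuracy is the Spearman correlation (average
ranks), computed per trait-environment combination within each partition and
averaged across partitions; the grand average is the mean of the
per-combination means.  Spearman is invariant to the $\exp$ and $r$ scaling,
so accuracies are unaffected by the offset conventions.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to give stable Monte Carlo behavior
on a single desk core: the successive-conditional test uses 12,000 forward
draws against 24,000 sweeps of the tiny model; parameter recovery fits one
S1 replicate at $J = 50$ with a 4,000-iteration chain (2,000 burn-in, thin
5); the cross-validation experiment runs both scenarios at full $J = 200$
with 10 partitions and the same reduced chain, one testing fraction per
scenario.  Full-length analysis chains default to 40,000 iterations with
20,000 burn-in and thinning 5 (4,000 retained samples).

## Known limitations

* Estimating the NB size $r$, Metropolis-within-Gibbs fallbacks, and
  zero-inflated or hurdle extensions are out of scope; $r$ is a fixed
  approximation device.
* Dense-$G$ interaction updates solve an $IJL$-dimensional system per sweep;
  beyond a few hundred lines this is the dominant cost and a sparse or
  low-rank treatment would be needed.
* The $\Sigma_t$ conditional pools the quadratic forms of both $b_1$ and
  $b_2$, the conjugate reading of the joint; the grid-proportionality and
  successive-conditional checks validate exactly this pooled form.
* Chains on weakly identified scale splits (e.g. $\Sigma_E$ against
  $\Sigma_t$ inside $\Sigma_E \otimes G \otimes \Sigma_t$) mix slowly; the
  trace and autocorrelation exports exist for precisely that diagnosis.
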