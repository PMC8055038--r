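---
title: "Methods: the individual-level deprivation index model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the individual-level deprivation index model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the sampler, the design choices that
were genuinely open, and what the validation on synthetic cohorts does
and does not establish.

## The model and its assumptions

Each participant carries a scalar latent trait $\theta_i \sim N(0,1)$,
interpreted as an individual deprivation level. Each of $J = 9$
dichotomous deprivation-direction items in province $k$ has an intercept
$\alpha_{jk}$ and a discrimination $\beta_{jk} > 0$, and the response
arises from a latent utility

$$x^*_{ijk} = \alpha_{jk} + \beta_{jk}\,\theta_i + \varepsilon_{ijk},
\qquad \varepsilon \sim N(0,1), \qquad x_{ijk} = 1\{x^* > 0\},$$

so that $\Pr(x = 1 \mid \theta) = \Phi(\alpha_{jk} + \beta_{jk}\theta)$.
The fitted response function is **probit** throughout, matching the
latent-utility formulation; item characteristic curves (ICCs) are
reported with the inflection location $-\alpha/\beta$ (where the
endorsement probability is exactly one half) and slope governed by
$\beta$, so the familiar difficulty/discrimination reading carries over.
A logistic ICC parameterization in which the intercept itself is the
inflection point is sometimes written for this model family; it is not
consistent with the latent-normal statement, and we resolve the
discrepancy in favour of the probit likelihood, reporting
$(-\alpha/\beta,\ \beta)$ as the curve landmarks.

Key assumptions: items are conditionally independent given $\theta$
(local independence); every item is coded so that 1 is the
deprivation-associated level, making all item–trait relationships
monotone increasing; and missingness is handled by complete-case
analysis (no imputation), which is unbiased under MCAR.

### Identification

$\theta \sim N(0,1)$ fixes location and scale. The reflection
$(\theta, \beta) \leftrightarrow (-\theta, -\beta)$ is removed by
constraining every $\beta_{jk} > 0$, which is substantively justified by
the deprivation-direction coding. Consequently persons whose responses
are all 1 receive a higher posterior index than persons whose responses
are all 0.

### Priors

The data give no information to separate province-level item parameters
without some pooling structure, and the literature this model follows is
silent on priors, so these are package choices:

* pooled variant: $\alpha_j \sim N(0, 2^2)$,
  $\beta_j \sim N^+(0, 2^2)$ (positive-truncated);
* hierarchical variant: $\alpha_{jk} \sim N(\mu^\alpha_j, \tau^{\alpha2}_j)$,
  $\beta_{jk} \sim N^+(\mu^\beta_j, \tau^{\beta2}_j)$, with hypermeans
  $\sim N(0, 2^2)$ and hypervariances
  $\tau^2 \sim \text{Inv-Gamma}(2, 1)$ for conjugacy.

On the probit scale, intercepts beyond $\pm 4$ correspond to
prevalences outside (0.003%, 99.997%), so a prior standard deviation of
2 is weakly informative. The Inv-Gamma(2, 1) hypervariance prior has
mean 1: it allows substantial province differences and does not force
pooling. A consequence worth knowing (see *Limitations*): when the data
are truly common across provinces, the hierarchical model's
province-level parameters still move at the scale the hyperprior
permits, so its WAIC carries an overhead of roughly 5–30 on a cohort of
800–1800 relative to the pooled model rather than tying it. When
provinces genuinely differ at the magnitudes seen in the calibrated
cohort, the hierarchical model wins by hundreds of WAIC units, so model
selection is unambiguous in the regime the index targets.

## The sampler

Fitting is by Markov chain Monte Carlo with latent-utility data
augmentation, which makes every full conditional available in closed
form:

1. **Utilities**: $x^*_{ij} \mid \cdot \sim N(\alpha + \beta\theta_i, 1)$
   truncated to $(0,\infty)$ if $x = 1$ and $(-\infty, 0]$ if $x = 0$.
   Truncated-normal draws use the inverse-CDF method with all tail
   arithmetic in log space, so cells with $|\alpha + \beta\theta| > 6$
   still produce finite draws on the correct side.
2. **Traits**: $\theta_i \mid \cdot \sim
   N\!\big(V_k \sum_j \beta_{jk}(x^*_{ij} - \alpha_{jk}),\ V_k\big)$,
   $V_k = (1 + \sum_j \beta_{jk}^2)^{-1}$.
3. **Item parameters**: per (item, province) cell, the posterior of the
   unit-variance regression of $x^*$ on $(1, \theta)$ under the normal
   priors is a bivariate normal truncated to the half-plane
   $\beta > 0$. That distribution is sampled *exactly and
   independently of the current values*: $\beta$ from the
   positive-truncated marginal of the joint posterior, then $\alpha$
   from its Gaussian conditional given the drawn $\beta$. (A naive
   $\alpha\mid\beta$, $\beta\mid\alpha$ scan is also exact but mixes
   badly for rare items; the truncated-marginal route costs the same
   and draws the cell afresh each cycle.)
4. **Hyperparameters** (hierarchical): conjugate normal updates for the
   hypermeans and inverse-gamma updates for the hypervariances.

Three additional moves, each leaving the posterior exactly invariant,
address the slow directions that plain data augmentation leaves behind:

* a **recentering move** sampling a translation $c$ along the
  likelihood-invariant orbit $\theta \to \theta - c$,
  $\alpha \to \alpha + \beta c$ from its exact Gaussian orbit
  conditional (a generalized-Gibbs move under the translation group);
* a **rescaling move**: one symmetric random-walk Metropolis step on
  $t = \log s$ along the orbit $\theta \to \theta/s$,
  $\beta \to s\beta$, targeting the orbit density with the
  multiplicative Haar measure;
* a **marginal refresh** of each item cell: one random-walk Metropolis
  step on $(\alpha_{jk}, \beta_{jk})$ targeting the cell posterior with
  the utilities integrated out (Bernoulli-probit likelihood). Because
  $x^*$ is regenerated from its full conditional at the start of the
  next cycle before any reuse, this is a valid partially collapsed
  update. It is what makes extreme-prevalence cells (e.g. a 2.6%
  item in one province) mix: their long $x^*$–$(\alpha,\beta)$
  autocorrelation disappears. Proposal scales are fixed per cell from a
  Laplace (observed-information) approximation at crude initial
  estimates, so the proposal is state-independent and hence symmetric.

The correctness of this machinery is tested three ways: exact
closed-form checks of every conjugate conditional; a Geweke-style
successive-conditional simulation (the full scan, run with data
regenerated each cycle, must preserve the prior — a sign error or
invalid move shifts the moments detectably); and bit-level equivalence
between the compiled chain and a pure-R reference built from the
exported step functions at the same seed.

Chains start from probit-transformed item prevalences, unit
discriminations, and standardized response sums, jittered per chain;
every chain's stream derives deterministically from the master seed, so
fits are bit-reproducible. Convergence is monitored with split R-hat
(floored at 1, since the raw estimator can dip below 1 by $O(1/n)$
noise) and a Geyer initial-positive-sequence effective sample size. At
the default 4 chains × 5000 iterations (2500 burn-in, thin 1) on the
calibrated cohort, all item parameters reach split R-hat < 1.05.

## Model comparison

WAIC is computed from the pointwise log-likelihood with one
person–item response as the unit ($n = N \cdot J$), conditional on the
sampled $\theta_i$ — the standard pointwise usage for this model class:
$\text{lppd} = \sum_i \log \text{mean}_s \exp(\ell_{si})$ (via
log-sum-exp), $p_{\text{WAIC}} = \sum_i \text{var}_s(\ell_{si})$,
$\text{WAIC} = -2(\text{lppd} - p_{\text{WAIC}})$, with standard error
$\sqrt{n \cdot \text{var}_i(\text{waic}_i)}$. A difference of at least
5 is flagged substantial. The same `waic()` implementation serves the
index models and the outcome models.

## Variable screening

The screening stage is diagnostic, not decision-making: all pairwise
Pearson χ² tests (no continuity correction, α = 0.05,
pairwise-complete rows) and a multiple correspondence analysis of the
N × 2Q indicator matrix (standardized residuals, SVD; eigenvalues are
squared singular values; total inertia for Q binary variables is
exactly 1; Benzécri-adjusted inertias available behind a flag, raw by
default). The final item set is an explicit configuration input — the
published nine-item set is the default — because the original selection
combined statistics with expert opinion, which no algorithm here should
pretend to reproduce.

## Outcome model

Second-visit non-attendance is regressed on the index by Bayesian
logistic regression under independent $N(0, 2.5^2)$ priors, sampled by
random-walk Metropolis with a proposal covariance adapted during
burn-in only (frozen afterwards, so the chain is a fixed-kernel
Markov chain when draws are retained). The index enters as the
plug-in posterior mean of $\theta_i$ — a two-stage analysis that
ignores index uncertainty, matching the single-number use of the score.
Odds ratios are reported as the posterior mean of the exponentiated
draws with 2.5/97.5% quantile intervals. The comparison of the
index-only model against the all-components model uses the same WAIC
machinery and threshold.

## The synthetic cohort generator

Because the source cohort is not public, every validation runs on
synthetic cohorts with known truth. The calibrated configuration
reproduces the published structure: four provinces of 613, 409, 563 and
197 participants; per-item, per-province marginal prevalences matched
to the published baseline table through the closed-form link
$\text{prev} = \Phi(\alpha / \sqrt{1 + \beta^2})$; discriminations
drawn once from LogNormal(0, 0.3²) and frozen in a plain-text fixture
(so recovery tests have a fixed truth); MCAR masking at the published
per-cell missingness rates (0–13%, with one 28% cell); and a binary
outcome from a logistic model on the true trait with a per-unit odds
ratio of 1.17 and the intercept solved by root finding so the marginal
non-attendance rate is 30%.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: informative (MNAR) missingness;
residual dependence between items beyond the shared trait (real
indicators such as the two injection-drug-use items are likely locally
dependent); measurement error or drift in the raw variables; and any
longitudinal visit structure beyond the single binary outcome.
Parameter-recovery results (trait correlation ≈ 0.85, 95% interval
coverage near nominal at the full cohort size) show the estimator works
when the model is true, which is the most a simulation can show.

## Numerical and scale choices

* Truncated-normal sampling by inverse CDF with log-space tails; draws
  are clamped to the truncation boundary against rounding.
* Income dichotomization places the boundary value ($1500/month)
  in the non-deprived class, matching the "equal to or more than"
  convention of the source threshold.
* The small-province filter defaults to a minimum of 100 participants,
  which reproduces the published exclusion of the two provinces with 13
  and 47 participants; the original analysis states no explicit
  threshold.
* Pipeline stages derive child seeds deterministically from the master
  seed and the stage name, so adding a stage never shifts another
  stage's stream.
* Test and validation runs are scaled to keep the whole suite
  comfortably within a desktop coffee break: tiny-instance oracle
  checks at N = 6 with dense-grid quadrature; pooled recovery at
  N = 400; model-selection replicates at N = 800 with 2 chains × 2000
  iterations; full-cohort recovery at 2 chains × 2500; the default
  4 × 5000 configuration is exercised once for convergence.

## Known limitations

* With the Inv-Gamma(2, 1) hypervariance prior, the hierarchical model
  does not collapse onto the pooled model when provinces are truly
  identical: its WAIC then exceeds the pooled model's by more than the
  substantial-difference threshold. Model selection therefore behaves
  asymmetrically — decisive when provinces differ, mildly biased toward
  the pooled model when they do not. A spike-like or
  stronger-shrinkage hyperprior would trade this against sensitivity to
  real province differences; we keep the conjugate default and document
  the behaviour.
* The two-stage outcome analysis ignores posterior uncertainty in the
  index; intervals for the odds ratio are accordingly a little
  narrow.
* Complete-case analysis is only defensible at the low missingness
  rates the cohort exhibits; the package deliberately offers no
  imputation.
* The index is cohort-relative: scores are identified only up to the
  N(0,1) trait scale of the fitted sample and do not transfer to other
  populations without refitting.
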