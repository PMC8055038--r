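# deprivindex

Estimating an individual-level deprivation index for HIV/HCV coinfected
cohort participants from dichotomous social, material and lifestyle
indicators, with province-varying item behaviour.

## The problem

Deprivation is a latent construct: no single variable measures it, and
area-based indices assign every resident of a census area the same score,
which fits marginalized populations poorly. This package estimates a
per-person deprivation score from nine binary indicators (low income,
low education, unemployment, not identifying as gay or bisexual,
Indigenous status, injection drug use ever and in the last 6 months,
incarceration history, past psychiatric hospitalization), all coded so
that 1 is the deprivation-associated level.

## The model

A two-parameter probit item response theory (IRT) model. Person *i* in
province *k* carries a latent trait θ*ᵢ* ~ N(0, 1) — the deprivation
index. The response to item *j* arises from a latent utility

&nbsp;&nbsp;&nbsp;&nbsp;*x\*ᵢⱼₖ* = α*ⱼₖ* + β*ⱼₖ* θ*ᵢ* + ε, ε ~ N(0, 1),
*xᵢⱼₖ* = 1{*x\** > 0},

so P(*x* = 1) = Φ(α*ⱼₖ* + β*ⱼₖ* θ*ᵢ*). α*ⱼₖ* governs how commonly an item
is endorsed (the item characteristic curve's inflection sits at
θ = −α/β), and β*ⱼₖ* > 0 is the discrimination. Two variants are fitted
and compared by WAIC: a **pooled** model (α*ⱼ*, β*ⱼ* common across
provinces) and a **hierarchical** model in which (α*ⱼₖ*, β*ⱼₖ*) vary by
province around per-item hypermeans, letting the data decide how much
provinces differ. Fitting is by a data-augmentation Gibbs sampler with
exact conjugate updates (compiled core, with a pure-R reference
implementation of every step used in the tests), plus recentering /
rescaling orbit moves and a collapsed Metropolis refresh for
extreme-prevalence items.

Around the core model the package provides: a dichotomization and
complete-case preprocessing stage, a variable-screening stage (pairwise
Pearson χ² tests and multiple correspondence analysis of the indicator
matrix), item characteristic curve and discrimination summaries, a
Bayesian logistic regression linking the index to second-visit
non-attendance (odds ratios as means of exponentiated draws), and a
calibrated synthetic-cohort generator with known ground truth — the
original cohort data are not public, so a fictitious sample ships with
the package and arbitrarily large cohorts can be simulated.

## Worked example

```r
library(deprivindex)

raw   <- read_cohort(fictitious_sample_path())   # packaged synthetic sample
items <- dichotomize(raw, ccc_rules())           # 19 candidates -> 0/1 items
cc    <- complete_cases(items, core9_items())   # the nine retained items
cc$report
#> Exclusion report: 400 -> 400 (province filter) -> 346 (complete cases)

fit <- irt_deprivation(cc$data, items = core9_items(),
                       variant = "hierarchical",
                       mcmc = mcmc_control(iterations = 2000, burn_in = 1000,
                                           chains = 2, seed = 1))
fit
#> Deprivation index model (hierarchical probit 2PL)
#>   346 persons, 9 items, 4 province group(s)
#>   2000 retained draws from 2 chain(s); max split R-hat 1.075

head(discrimination_table(fit), 3)[, 1:4]
#>          item province beta_mean   beta_sd
#> 20 indigenous       SK  2.093800 0.8180517
#> 17 indigenous       BC  1.780916 0.5762541
#> 7  low_income       QC  1.632099 0.4383938

idx <- posterior_index(fit)     # per-person index summaries
or_fit <- bayes_logistic(cc$data$outcome, cbind(index = idx$theta_mean),
                         mcmc = mcmc_control(iterations = 3000,
                                             burn_in = 1500, chains = 2,
                                             seed = 2))
or_fit
#> Bayesian logistic regression (N = 346, 1 covariate(s); acceptance 0.37)
#> Odds ratios (posterior mean of exponentiated draws, 95% CrI):
#>  covariate or_mean ci_lo ci_hi
#>      index    1.01  0.76  1.32
```

The discrimination table says, for example, that Indigenous status
separates more- from less-deprived participants most sharply in
Saskatchewan and British Columbia, while the odds-ratio row estimates how
a one-unit increase in the index changes the odds of missing the second
clinic visit (at n = 346 the interval is wide; at the full cohort size
the generator's calibrated effect of 1.17 is recovered — see below).
`run_pipeline()` chains all of these stages, writes every stage artifact
to disk, and compares pooled and hierarchical fits by WAIC with the
difference-of-5 substantial-change rule.

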