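---
title: "Multi-level behavioral variance: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level behavioral variance: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Workers of a social-insect colony differ consistently in behavior
(among-individual variation, "personality"), colonies differ from one
another (among-colony variation), and a single worker differs from trial to
trial around its own mean (residual intraindividual variation, rIIV — its
inverse is often called predictability). `antvar` quantifies all three
levels for repeated behavioral assays of *Myrmica*-type ant colonies —
activity (path length, cm), meandering (mean absolute turning per distance,
degrees/cm), exploration (novel grid squares entered), aggression (ordinal
0–3 score against a dead non-nestmate) and colony-level nest-displacement
efficiency (seconds until the last larva reaches a new nest chamber) — and
relates behavior to colony productivity (brood counts).

The sampling design the package models and simulates: two habitat types
(seminatural vs. invaded meadows) with 12 and 11 colonies, 12 focal workers
per colony, each worker tested three times per assay; colony sizes span
219–5964 workers; conspecific nest density 0–9 and allospecific density 0–3
per 9 m²; three nest-displacement trials per colony.

## The double hierarchical model

For one trait, trial value $y_{ijk}$ of worker $j$ in colony $k$:

$$y_{ijk} = \beta_0 + \beta_1\,\text{worker size} + \beta_2\,\text{colony
size} + \beta_3\,\text{conspecific nests} + \beta_4\,\text{allospecific
nests} + \beta_5\,\text{habitat} + \beta_6\,\text{trial number} +
\mathrm{ID}_{\mu j} + \text{colony}_k + \varepsilon_{ijk}$$

$$\log \sigma_{\varepsilon j} = \gamma_0 + \gamma_1\,\text{worker size} +
\dots + \gamma_5\,\text{habitat} + \mathrm{ID}_{\sigma j}, \qquad
(\mathrm{ID}_{\mu j}, \mathrm{ID}_{\sigma j}) \sim \mathcal N_2(0, \Omega)$$

The individual intercepts of the mean and of the log residual SD are drawn
jointly with free covariance, so the model estimates whether individuals
with high mean expression are also more (or less) predictable:
$r_{\mathrm{Int,rIIV}} = \mathrm{cov}/(\sigma_{\mathrm{ID}\mu}\,
\sigma_{\mathrm{ID}\sigma})$. Nest displacement uses the same structure
with colony intercepts on both submodels (its "residual" is within-colony
variation across the three displacement trials). All responses and
continuous covariates are standardized; habitat is coded 0 = seminatural,
1 = invaded; the trial-number covariate enters the mean submodel only.

### Sampler

`fit_dhglm()` runs a Metropolis-within-Gibbs sampler: conjugate Gaussian
draws for the fixed mean effects and both sets of mean intercepts;
vectorized adaptive random-walk Metropolis for the dispersion effects, the
log-SD intercepts and the variance/correlation parameters (random-effect
SDs on the log scale, the $\Omega$ correlation on the $\tanh^{-1}$ scale,
with the appropriate Jacobians). Proposal scales adapt toward a 0.44
acceptance rate during burn-in only, so the post-burn-in chain is a fixed
Markov kernel.

Group-constant covariates (habitat, colony size, nest densities, worker
size) are strongly coupled a posteriori with the random intercepts, which
stalls a plain Gibbs sweep. Each iteration therefore adds interweaving
translation moves: a proposal shifts one coefficient by $\delta$ and
subtracts $\delta x$ from the matching group intercepts, leaving the
likelihood unchanged so the acceptance ratio involves only priors. This
raised the slowest effective sample sizes by roughly an order of magnitude
at no measurable cost.

Priors: $\mathcal N(0, 10^2)$ on all $\beta$ and $\gamma$ (diffuse relative
to standardized data), half-$\mathcal N(0,1)$ on random-effect SDs,
uniform on the $\Omega$ correlation. Convergence is checked with split-
$\widehat R$ (< 1.1) and effective sample size (> 200); `summarize_fit()`
warns when either fails. Posterior intervals are equal-tailed quantile
intervals. Default run length is 4 chains × 10,000 iterations (5,000
burn-in, thin 5); the workflow scripts and tests use 2 chains × 2,000–3,000
iterations, which the interweaving moves make sufficient at the study's
data size (828 trials); both are configuration choices, not limits of the
method.

The likelihood-ratio tests for the random intercepts
(`random_intercept_lrt()`) use ML fits from `lme4` with the 50:50
$\chi^2_0/\chi^2_1$ boundary mixture for the p-value, since the null pins a
variance to the edge of its parameter space.

## Behavioral syndromes

`fit_multitrait_model()` stacks the traits of each (worker, trial-series)
cell as a multivariate Gaussian response with habitat as fixed effect and
unstructured covariance matrices at the colony, individual and residual
levels. The Gibbs sampler is fully conjugate: matrix-normal draws for
fixed and random effects, inverse-Wishart draws for each covariance with
prior $\mathrm{IW}(p+1, I)$ — chosen because its implied marginal prior on
every correlation is uniform on $(-1,1)$, the matrix analogue of the
uniform-correlation prior used in the univariate model. Correlations and
their credible intervals come from transforming every covariance draw
(`decompose_correlations()`), which keeps each draw positive definite by
construction. The habitat effect is tested with the posterior sign
probability `fixed_effect_pmcmc()`.

The five-trait form adds colony-level nest displacement with colony as the
sole random effect. Because the individual traits are measured on worker
trials and displacement on colony trials, the response rows are unbalanced;
missing trait entries are imputed by data augmentation inside the sampler
from their conditional normal. Only the among-colony correlations of this
model are interpretable — its "residual" mixes within-worker and
within-colony variation measured on different units — and the workflow
reports only those.

## Repeatability

`estimate_repeatability()` computes the intraclass correlation
$R = \sigma^2_{\text{group}} / (\sigma^2_{\text{group}} +
\sigma^2_{\text{res}})$ from a Gaussian ML random-intercept model (`lme4`),
with individual (its 3 repeats) or colony (its 12 workers × 3 repeats) as
the grouping factor. Confidence intervals use 1,000 parametric-bootstrap
refits by default; p-values use a randomization test with group labels
permuted across observations, $p = (1 + \#\{R_\pi \ge R\})/(1 + N_\pi)$.
An alternative `scheme = "block"` permutes whole individuals across
colonies for the colony level, since the exchangeable unit there is
arguably the worker; the observation-level scheme is the default because it
is the standard exchangeable null and the block variant is provided for
sensitivity analysis.

## Productivity models

Colony level: production counts (total; workers = larvae + worker pupae;
gynes = gyne pupae + winged gynes; males = male pupae + winged males) are
regressed on habitat plus the standardized colony means and SDs of the five
traits. A Poisson GLM is fitted first and replaced by a negative-binomial
ML fit when the Pearson dispersion statistic exceeds 1.5 — the
overdispersion rule needs a numeric cutoff and 1.5 is a conventional
middle ground. Stepwise bidirectional AIC selection (`MASS::stepAIC`) is
available; the males model is skipped when too few colonies produced males
for a stable fit. We treat the "males" component as male pupae plus winged
males throughout, the composition consistent with the worker and gyne
components.

Individual level: each (worker, trial-series) row carries its colony's
production count, regressed on the four trial-level traits with an
individual random intercept — an NB GLMM (Laplace ML via `glmmTMB`), with
an automatic, message-documented fallback to a Gaussian LMM when the NB
fit does not converge (which genuinely happens when the response is
colony-constant). All-subsets AICc selection over the fixed effects is
implemented in-package: subsets are enumerated (with a combinatorial guard
at 20 terms), ranked by $\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$,
ties broken toward fewer parameters, and the full path logged.

## The synthetic-data generator

The generator (`generate_dataset()`, `generate_nest_displacement()`,
`generate_productivity()`) exists so that every estimator above can be
verified by parameter recovery: it draws data from exactly the model the
analysis assumes, at the study scale or any configured scale, and stores
every realized random effect in a truth side-table. Design choices:

* **Defaults are the study conditions.** Sample sizes, covariate ranges
  and the generating coefficients/variances default to field-realistic
  values at the study design scale. Two dispersion parameters for
  aggression were moderated to the interior of their plausible ranges
  because the extreme point values implied residual SDs spanning ten
  orders of magnitude — an artifact of fitting a bounded ordinal score as
  a Gaussian; and the meandering mean–rIIV correlation default is 0.71,
  the midpoint of its plausible interval, because the point value printed
  for that quantity is internally inconsistent with its own interval.
* **Colony sizes are log-uniform** over the configured range: only the
  median and extremes of real colony sizes are known, and log-uniform
  matches the observed right skew without asserting an unreported
  distribution. Nest counts are truncated-Poisson; worker head width is
  Normal clipped to positive with placeholder mean 1000 µm, SD 60 µm (no
  empirical distribution is available).
* **Cross-trait structure by construction.** Individual mean intercepts
  follow the configured among-individual trait correlation matrix; each
  trait's log-SD intercept is built from its own mean intercept with the
  configured within-trait correlation plus an independent innovation. This
  guarantees a positive-definite joint covariance for any admissible
  configuration — a fully free 8×8 specification can easily be
  inconsistent (e.g. two strongly correlated mean intercepts cannot both
  be near-perfectly but oppositely correlated with independent log-SD
  intercepts).
* **Latent scale vs. raw units.** Traits are generated on the
  standardized analysis scale and mapped to raw units through fixed
  affine/`log1p` scales; aggression is kept continuous on the latent
  scale by default (so the Gaussian model assumptions hold exactly in
  recovery tests) with optional discretization to the 0–3 score.
  Recovery tests fit the latent-scale values directly; re-standardizing a
  finite sample would rescale every generating coefficient by the sample
  SD and bias recovery by a few percent.
* **Seeding.** One master seed drives a deterministic substream per stage
  (dataset, displacement, productivity, each MCMC chain), so stages are
  individually reproducible and chains are independent but repeatable.
* **Log transform is `log1p`** for aggression, meandering and
  displacement: aggression scores include 0, so a plain log is undefined;
  one consistent rule avoids trait-specific special cases.

What the generator does *not* emulate: ordinal measurement error in
aggression (unless discretization is enabled), movement paths or any
spatial process, temporal carry-over between assays, and death/escape of
workers (incomplete individuals can be created by deleting rows, as the
tests do). Passing recovery tests therefore show the estimators are
correct under the model's assumptions — not that real ant data satisfy
those assumptions.

## Numerical choices and degenerate inputs

* Standardization is an error on zero-variance columns; model fitting
  refuses non-standardized covariates (|mean| > 0.01 or |SD − 1| > 0.01)
  and singular designs.
* Variance "support" flags in summaries use a lower-CrI floor of 0.01
  rather than 0, since a variance CrI never contains exactly 0.
* Spearman screening uses average ranks for ties and the t approximation
  for p-values; the trial-number covariate is the within-assay index 1–3.
* In `decompose_correlations()` draws with a zero variance are dropped and
  counted rather than propagating NaNs.
* Complete-case filtering drops whole individuals, so every retained
  individual contributes exactly 12 rows (4 assays × 3 repeats).
* The colony-level "workers vs. trials" ambiguity (incomplete individuals
  contribute to colony trait SDs or not) is exposed by simply passing
  either the filtered or the unfiltered table to
  `colony_trait_summaries()`; the workflow uses the unfiltered table for
  productivity and the filtered one everywhere else.

## Problem sizes used by the shipped workflow and tests

The analysis scripts and the acceptance checks run the full study design
(23 colonies × 12 workers × 3 repeats) with 2 chains × 2,000–3,000 MCMC
iterations for the hierarchical models, 20 replicate datasets for coverage
checks, 200 colonies / 300 individuals for productivity recovery, and
100–1,000 resamples for bootstrap/permutation procedures. These sizes were
chosen so the whole suite runs on a laptop-class single core in minutes
while keeping Monte Carlo error well below the effect sizes being checked.

## Known limitations

* Three repeats per individual identify the dispersion submodel weakly;
  individual-level rIIV estimates lean on the half-Normal prior and should
  be read as shrinkage estimates (wide CrIs at the study scale).
* The DHGLM is Gaussian-only; no random slopes or spatial/temporal
  correlation structures are implemented.
* The five-trait syndrome model's non-colony levels are computed but not
  interpretable, and are flagged as such.
* Bootstrap CIs for repeatability are percentile intervals; no
  bias-correction is applied.
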