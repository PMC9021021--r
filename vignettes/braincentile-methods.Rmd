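---
title: "Normative brain charts with braincentile: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative brain charts with braincentile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincentile)
```

## The problem

Growth charts answer a simple question — *given this person's age and sex,
where does their measurement sit in the population?* — and have done so for
height and weight for over a century. For brain morphometry the question is
harder: measurements are aggregated across dozens of primary MRI studies
with different scanners, protocols and processing pipelines, ages span from
mid-gestation to late life, and both the typical value *and* the
between-subject spread of a phenotype change with age. `braincentile`
implements the statistical machinery for lifespan normative charts of
positive-valued phenotypes (tissue volumes in mm³, surface area in mm²,
cortical thickness in mm) under exactly these conditions, and the
downstream analyses such charts enable: centile scoring of individual
scans, harmonization of new studies, developmental milestones, and
case-control or heritability statistics on the centile scale.

## The model

A phenotype $Y > 0$ follows a three-parameter generalized gamma
distribution with density

$$f(y) = \frac{|\nu|\,\theta^{\theta} z^{\theta} e^{-\theta z}}
{\Gamma(\theta)\, y}, \qquad z = (y/\mu)^\nu, \qquad
\theta = \frac{1}{\sigma^2\nu^2},$$

chosen because it is a flexible positive-valued family whose special cases
are the two work-horses of anthropometric charting: $\nu = 1$ gives the
gamma distribution (shape $1/\sigma^2$, mean $\mu$) and $\nu \to 0$ the
log-normal $(\log\mu, \sigma)$. $\mu$ is a scale parameter in the
phenotype's own units, $\sigma$ is a dimensionless relative spread, and
$\nu$ tilts the skewness. Each distribution parameter gets its own linear
predictor (the distributional-regression, or GAMLSS, structure):

$$\log \mu = X_\mu \beta_\mu + \gamma_{\mu,\mathrm{study}}, \qquad
  \log \sigma = X_\sigma \beta_\sigma + \gamma_{\sigma,\mathrm{study}},
  \qquad \nu = \alpha_\nu,$$

where the fixed designs contain an intercept, indicator-coded sex
(reference female) and optionally a processing-version factor (in the
$\mu$ design only), plus a fractional-polynomial age basis; the
$\gamma$'s are Gaussian per-study random intercepts,
$\gamma \sim N(0, \delta^2)$, absorbing scanner and protocol batch
effects on both the location and the spread. $\nu$ is a free intercept
with no covariates: skewness is weakly identified compared with location
and scale, and estimating age- or study-varying skewness would demand far
more data than it repays.

**Age.** Internally age is measured in years *post-conception*
($x = \texttt{age\_days}/365.25$), which keeps $x$ strictly positive so
logs and negative powers are defined for foetal scans; ages are *reported*
relative to birth using the 40-week convention
(`(age_days - 280)/365.25`), so prenatal milestones come out negative.
The conversion constant is a convention, stated here once and used
everywhere.

**Fractional polynomials.** The age trend of each moment is a fractional
polynomial over the standard power set
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (power 0 meaning $\log x$), with a
repeated power $p$ contributing $x^p, x^p\log x, x^p(\log x)^2$. Orders
up to 3 give 164 candidate bases per moment (plus the empty basis);
compared with spline smoothers this family is parametric, extrapolates
sanely, differentiates in closed form, and remains stable in the presence
of random effects.

## Estimation

`gg_gamlss()` maximizes the penalized log-likelihood in which the random
intercepts appear as coefficients with ridge weight $1/(2\delta^2)$. The
outer loop cycles:

1. a Fisher-scoring step for $(\beta_\mu, \gamma_\mu)$ — the expected
   information for $\log\mu$ is the simple weight $1/\sigma_i^2$;
2. a Laplace-marginal update of $\delta^2_\mu$: each study contributes a
   pseudo-observation $m_s = \hat\gamma_s + u_s/H_s$ with precision
   $H_s$ (the summed per-scan weights), and $\delta^2$ maximizes the
   one-dimensional marginal likelihood of
   $m_s \sim N(0, \delta^2 + 1/H_s)$. This update reaches the
   $\delta^2 = 0$ boundary cleanly when the data carry no study effect —
   a moment-style fixed-point update approaches that boundary only
   sublinearly;
3. the same two steps for $(\beta_\sigma, \gamma_\sigma, \delta^2_\sigma)$
   with the $\log\sigma$ score and weight
   $4\theta(\theta\psi'(\theta) - 1)$ (series-expanded for large
   $\theta$, where cancellation would otherwise lose the weight's small
   excess over 2);
4. a one-dimensional profile maximization for $\alpha_\nu$.

Every block step is guarded by step-halving on the penalized
log-likelihood, so the objective is non-decreasing across cycles up to
the line-search tolerance; the loop stops when the relative change falls
below $10^{-6}$ (at most 200 cycles; non-convergence is flagged on the
object, not thrown). Starting values are deterministic and scale-aware —
an OLS fit of $\log y$ on the $\mu$ design, its residual SD for the
$\sigma$ intercept, $\nu = 1$ — which makes refits bit-reproducible and
gives the equivariance property that multiplying $y$ by $c$ shifts only
the $\mu$ intercept by $\log c$. Values of $|\nu| < 10^{-5}$ are computed
through the log-normal limiting form throughout (density, CDF, quantile,
scores), since $\theta$ diverges as $\nu \to 0$.

Standard errors of the fixed effects come from the joint penalized
expected information at convergence (so the intercept's uncertainty
includes the between-study component), with the variance components held
at their estimates; percentile bootstrap over participants — resampled
with replacement *within study-by-sex strata*, preserving the design —
is the primary uncertainty mechanism for derived quantities such as
milestone ages.

**Model selection.** `select_gg_model()` ranks candidate power multisets
by BIC $= -2\ell + k\log n$ (with $\ell$ the unpenalized log-likelihood at
the posterior modes and $k$ counting fixed effects, the $\nu$ intercept
and one variance per active random term) in two stages: $\mu$ powers with
an intercept-only $\sigma$ trend, then $\sigma$ powers given the best
$\mu$. Exact ties break toward fewer parameters, then lexicographically
smaller powers; non-convergent candidates rank last. The search stage
runs at a slightly looser tolerance ($10^{-5}$, 60 cycles, one scoring
step per block) — only the ranking matters there — and the winner is
refit at the default tolerance.

## Centile scoring and new studies

A scan's centile is the fitted CDF evaluated at its observed value, i.e.
its rank within the age-, sex- (and, where applicable, study-) matched
normative population. Centiles are clamped to $[10^{-6}, 1 - 10^{-6}]$ so
downstream transforms (normal quantiles, logits) stay finite. Three
prediction modes are distinguished explicitly: *population* (all
$\gamma = 0$; the published chart), *study* (adds the fitted intercepts of
a study in the reference registry), and *offset* (adds supplied
link-scale shifts).

Out-of-sample data are harmonized by `new_study_offset()`: with all
population parameters frozen, each new study's log-likelihood is
maximized over shifts $(d_\mu, d_\sigma, d_\nu)$ — plain unpenalized ML,
with $|d_\nu| \le 2$ bounded against degeneracy on small studies and
optional exclusion of $d_\nu$ altogether. Offsets are *not* shrunk toward
the reference random-effect distribution; that is a documented package
choice, not a claim about any other implementation. Studies under 100
scans carry an explicit instability flag: in simulation the absolute
centile bias after offset fitting decays roughly as $1/n$, and below
about 100 scans the scale-offset estimate (sampling SD
$\approx 1/\sqrt{2n}$ on the log scale) is too noisy to trust.

## Milestones

Milestones are landmarks of the median (50th-centile) trajectory
evaluated on a daily grid ($h = 1/365.25$ years — finer than any
confidence interval the charts support): the age/value of the trajectory
peak, and the age of peak velocity, with velocity computed by central
differences (exact for locally quadratic curves; one-sided at the grid
ends). For headline, sex-agnostic milestones the female and male median
curves are averaged pointwise before taking the argmax; per-sex
milestones are available by passing a single sex. A monotone curve
returns the grid endpoint flagged `interior = FALSE` rather than an
error. The grey/white differentiation epoch is bracketed by the first
sign change of the median GMV−WMV difference and the later age of
maximal absolute difference. Bootstrap confidence intervals are
empirical 2.5/97.5 percentiles of per-replicate milestone ages, with
endpoint-maximum replicates excluded and counted.

## Cohort statistics on the centile scale

*Multivariate deviation (CMD).* The control group's centile vectors
define a mean, principal axes, and per-axis SDs; a subject's CMD is the
sum of absolute standardized distances from the control mean along those
axes (a city-block Mahalanobis distance; the classical Euclidean variant
is available via `type = "euclidean"`). Axes with numerically zero
variance are dropped with a warning, and the axis-sign convention
(largest-magnitude loading positive) makes references reproducible.

*Case-control tests.* Within each sex stratum, every group pair is
compared by a two-sided Monte Carlo permutation test on the difference of
group medians, $p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + n_{perm})$, with
Benjamini–Hochberg FDR across the pairs of the stratum and Cohen's $d$
from the pooled SD; the omnibus statistic is Welch's one-way $F$ with a
pooled-resampling (bootstrap) null, a documented stand-in for a
"non-parametric generalization" that is named but not fully specified in
the charting literature.

*Longitudinal stability* is the subject-level IQR of centiles across
sessions, with linear-interpolation quantiles (R type 7) fixed as the
rule so results reproduce across environments; single-session subjects
are excluded and counted.

*Twin heritability* uses double-entry Pearson pair correlations and
Falconer's $h^2 = 2(r_{MZ} - r_{DZ})$, clamped to $[0, 1]$, with a
percentile bootstrap over pairs. This is deliberately the simple
correlation-based estimator, not a full ACE likelihood model.

## What the synthetic cohorts emulate — and what they do not

The generators in `simulate_cohort()` and friends are the package's test
bed: multi-study cohorts with log-uniform lifespan age sampling (dense in
development, as aggregated MRI datasets are), Bernoulli sex, Gaussian
per-study intercepts on both $\log\mu$ and $\log\sigma$, generalized
gamma outcomes, longitudinal repeats with controllable centile drift,
ACE-structured twin pairs, and clinical groups whose $\log\mu$ shift is
solved (by inverting the CDF at a reference age) to land the case median
at a requested normative centile.

The default presets are *fixtures with realistic headline features*, not
estimates of any real cohort: `gmv_like` peaks at 5.90 years from birth
with its velocity peak near 5.1 months and ~12% between-subject spread at
a ~7.7×10⁵ mm³ scale; `wmv_like` peaks at 28.7 years (velocity peak
2.4 years); `ct_like` is a mm-scale metric peaking at 1.7 years. All use
the two-term basis $\log\mu = c_0 + c_1\log x - c_2\sqrt{x}$, which has a
single interior maximum at $x^\ast = (2c_1/c_2)^2$; the preset
coefficients were solved once from the intended peak and velocity-peak
ages and then fixed. Known divergences from real data: the late-life
decline of this two-term shape is much steeper than real senescent
change; study effects are exactly Gaussian and independent of age;
there are no quality-control artefacts, no cohort effects, and no
missingness. Passing tests therefore demonstrate the correctness of the
machinery under the stated model, not robustness to everything real
multi-site MRI can do.

Default study conditions used by the validation experiments (and the
acceptance script): 20 studies × 200 scans for recovery checks; 4 × 1250
(n = 5000) with the order-≤2 candidate space for selection consistency;
n = 500 new studies for offset recovery, with sizes
{25, 50, 100, 200, 400} × ~50–100 replicates for the bias-vs-size curve;
1000 null repetitions at 199 permutations for test calibration; 300 twin
pairs per zygosity over 20 worlds for heritability. These sizes are the
package's chosen experiment designs, balancing Monte Carlo error against
the precision each check asserts.

## Numerical choices and limitations

* $|\nu| < 10^{-5}$: log-normal limiting form everywhere; continuity at
  the boundary is tested to $10^{-4}$ relative.
* $\theta > 10^8$: series expansions replace
  $\log\theta - \psi(\theta)$ and $\theta\psi'(\theta) - 1$, which
  double-precision arithmetic cannot resolve directly.
* Quantiles for $\nu < 0$ invert the upper regularized incomplete gamma
  tail, preserving tail orientation.
* $\delta^2$ estimates at the floor ($10^{-10}$) are reported as
  boundary fits and not counted as parameters in BIC.
* The models are cross-sectional by design; longitudinal repeats are
  *scored*, never jointly modelled (no within-subject covariance).
* Out-of-sample offsets assume the new study is exchangeable with the
  reference population up to link-scale shifts; systematic age-varying
  biases are not representable.
* Regional (parcel-wise) phenotypes can be fitted one at a time with the
  same machinery, but no mass-fitting campaign or cross-region machinery
  is provided.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
tr  <- true_model("gmv_like")
dat <- simulate_cohort(tr, n_studies = 20, n_per_study = 200, seed = 1)
fit <- gg_gamlss(dat, tr$spec)
summary(fit)

centiles <- centile_score(fit, dat, mode = "study")
find_milestones(fit)

new <- simulate_new_study(tr, d_mu = 0.10, d_sigma = -0.05,
                          n = 500, seed = 2)
off <- new_study_offset(fit, new)
centile_score(fit, new, mode = "offset", offset = off)
```

The package's test suite runs exactly these kinds of experiments with
frozen seeds, and `scripts/acceptance.R` recomputes the headline
quantities from scratch; every number quoted above (peak ages, spread,
bias behaviour) is produced by that code, not asserted.
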