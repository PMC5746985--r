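---
title: "Peer-density surfaces and oral-health regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peer-density surfaces and oral-health regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerdensity)
```

## The scientific problem

Older adults' oral health may respond to the *peer density* of their
neighbourhood — the spatial concentration of other people of similar age with
whom social contact, support, and knowledge about local care resources can
flow. `peerdensity` implements an end-to-end pipeline for testing that
hypothesis in a geocoded screening cohort: it smooths census-block counts of
the 50+ population into continuous density surfaces, assigns each
participant an exposure at their residence, relates two oral-health outcomes
to that exposure with appropriate regression models, and handles item
missingness in the covariates by multiple imputation.

The two outcomes are:

* **dentition status**, an ordinal three-level variable derived from the
  count of missing teeth (out of 28, third molars excluded): 0 = functional
  dentition (0–8 missing), 1 = limited functional capacity (9–27), 2 =
  edentulous (all 28);
* **self-rated oral health**, the participant's own four-level rating
  collapsed to binary: 0 = poor, 1 = at least fair. The poor/fair cutpoint —
  rather than the more common fair/good one — reflects the observation that
  in underserved populations pain from untreated disease, not aesthetics,
  drives self-assessment.

## Kernel density estimation of peer density

Block-level counts of residents aged 50+ are attached to block centroids
$x_i$ with weights $c_i$. The exposure surface uses the quadratic
(Epanechnikov) kernel $K(u) = \tfrac34(1-u^2)$ on $|u|\le 1$, zero outside,
with bandwidth $h$ interpreted as a walking-scale radius of social
interaction. Four bandwidths are carried through the analysis — 0.25, 0.50,
1.00, 1.50 miles — defining four "spatial models" whose comparison probes
how local the relevant social network is.

The default `planar2d` normalization spreads each person's unit mass over
the disk of radius $h$ with the radially symmetric quadratic profile,

$$\hat f(x) = \sum_i c_i \, \frac{2}{\pi h^2}\Bigl(1 - \frac{d_i^2}{h^2}\Bigr)
  \quad (d_i \le h),$$

where $d_i$ is the planar Euclidean distance from $x$ to centroid $x_i$. The
constant $2/(\pi h^2)$ makes the per-person kernel integrate to one over the
plane ($\int_0^1 (1-r^2)\, 2\pi r\, dr = \pi/2$), so the surface has honest
units of persons per square mile and integrates to the total population —
a property the test suite verifies by numerical quadrature. A second mode,
`as_printed`, evaluates the literal univariate estimator
$(nh)^{-1}\sum K\!\left((x - x_i)/h\right)$ over persons; it is retained for
comparison but is not dimensionally a two-dimensional density, and the
summary statistics of real survey exposures cannot distinguish the two
conventions without the original census data. Exposure assignment is exact
at each residence (no rasterization); `kde_raster()` exists only as a
plotting convenience.

Numerical choices: a block at exactly distance $h$ contributes zero (the
kernel vanishes there, so the open/closed boundary question is immaterial);
no edge correction is applied at the study-region boundary, a documented
limitation shared with the standard practice this mirrors; coordinates must
already be projected to planar miles — geocoding and map projection are out
of scope.

## Regression models

**Ordinal outcome.** Dentition status is modelled by generalized
adjacent-categories logistic regression (GACLR): for adjacent categories
$j$ and $j+1$,

$$\ln\frac{P(Y = j+1)}{P(Y = j)} = \beta_{0j} + \beta_{1j}X_1 + \cdots +
  \beta_{qj}X_q,$$

with *category-specific* coefficients — no proportional-odds constraint —
so a covariate may, say, raise the odds of limited function relative to
functional dentition while lowering the odds of edentulism relative to
limited function. Each $\exp(\beta_{kj})$ is directly an adjacent-pair odds
ratio, and the odds ratio for the extreme contrast (edentulous vs
functional) is the product of the two panel odds ratios.

The fitter exploits the exact reparametrization to a baseline-category
multinomial logit: with category 0 as baseline, the multinomial linear
predictors are the cumulative sums of the panel predictors, so the panel
coefficients are successive differences of multinomial ones and the
covariance transforms linearly. Maximization is by damped Newton iterations
on the multinomial likelihood (observed information, step-halving on any
likelihood decrease), run to gradient norm $10^{-8}$ with a cap of 100
iterations; covariate columns are internally rescaled to unit magnitude so
this stopping rule is meaningful when density (order $10^4$) and binary
indicators share a design. Tests verify the fit against an independent
generic-optimizer maximization of the adjacent-categories likelihood, the
closed-form cross-product odds ratios of a saturated contingency table, and
the binary-logit limit with two categories.

**Binary outcome.** Self-rated oral health uses standard ML logistic
regression (IRLS via `stats::glm.fit`); apparent separation or
non-convergence triggers a lightly ridge-penalized refit with a warning.
Goodness of fit for both models is summarized by McFadden's pseudo-$R^2 =
1 - \hat\ell/\hat\ell_0$ against the intercept-only null.

**Covariates** (reference categories first): gender (male), race/ethnicity
(Hispanic; non-Hispanic White, non-Hispanic Black, Other), age in years
(continuous), smoking (current; former, never), Medicaid dental coverage
(no), private dental insurance (no), education (primary; high school,
college), plus one density exposure column per spatial model.

## Multiple imputation

Missingness in the screening covariates is substantial (up to ~25% for
smoking status) and is handled by chained-equations multiple imputation
under a missing-at-random assumption, with `m = 10` completed datasets.
Three conditional models are used by variable type, each *proper* in the
sense that parameters are drawn from a posterior before the value is drawn:

* **continuous (age)** — predictive mean matching: a linear model on the
  five most correlated predictors fitted to complete cases; residual
  variance drawn from its scaled inverse-$\chi^2$ posterior and
  coefficients from the conditional normal (noninformative prior); the
  recipient receives the observed value of the *single* donor whose
  predicted mean (donors scored at the ML estimate, recipients at the
  posterior draw) is nearest in squared distance, ties broken uniformly at
  random. Imputed values are therefore always observed values.
* **binary (gender, Medicaid, private insurance)** — logistic regression on
  complete cases with an asymptotic-normal posterior draw of the
  coefficients, then a Bernoulli draw at the fitted probability.
* **categorical (race/ethnicity, smoking, education)** — multinomial logit
  with the last category as baseline, asymptotic-normal posterior draw,
  categorical draw from the fitted probabilities. With two categories this
  reduces exactly to the logistic model (tested to $10^{-10}$).

Predictors are the 5 most highly correlated variables with the target,
ranked by absolute pairwise-complete Pearson correlation on numerically
coded columns; a multi-category variable is expanded to indicators and
scores its best indicator. This mixed-type correlation rule is a documented
package choice (the selection criterion's exact metric for mixed types is
not standardized), as are the chaining details: 10 sweeps in the fixed
sweep order gender, race/ethnicity, age, smoking, Medicaid, private
insurance, education; missing cells initialized by draws from the observed
marginal; predictor sets computed once on the original incomplete data, not
adaptively per cycle; independent chains per imputation with sub-seeds
derived from one master seed.

Outcomes are *not* imputed in the default mode: models use complete cases
on the outcome with imputed covariates. The rationale is that outcome
missingness here arises from opting out of an examination (plausibly
completely at random) or may itself be a distinct state (not knowing one's
oral health), while covariate missingness is survey item nonresponse. Since
outcomes are never completed mid-sweep in this mode, they are also excluded
from the predictor pool; in `impute_all` mode they join both. A
`complete_case` mode performs listwise deletion for sensitivity comparison.

## Pooling and derived effects

Per-imputation fits are combined by Rubin's rules on the log-OR scale:
pooled estimate $\bar q$, within-variance $W$, between-variance $B$, total
$T = W + (1 + 1/m)B$, with Barnard–Rubin small-sample degrees of freedom
(complete-data df $n - k$) for the $t$-based intervals and p-values, then
exponentiated. The pooling formulas and Wald-interval construction are
package decisions — the methodology literature this follows reports only
that per-dataset analyses are combined. McFadden's $R^2$ under multiple
imputation is reported as the mean of per-imputation values. Significance
stars use strict thresholds: `***` p < 0.01, `**` p < 0.05, `*` p < 0.10.

Because a per-unit odds ratio for a variable measured in persons per square
mile is visually indistinguishable from 1, effects are rescaled:
`scaled_or(or, delta)` gives the OR per `delta` units (one sample SD of the
exposure; one decade of age), `combined_or()` multiplies the two panel ORs
for the extreme dentition contrast, and `percent_change()` reports
`round(100 (OR - 1))`, half away from zero. These operations reproduce,
from the published per-unit ORs and exposure SDs, every derived number in
the source analysis (16%/17%/10% density reductions, 116% Medicaid
increase, 88% per-decade age increase, and so on); `percent_change(1/x)
\neq -percent_change(x)` in general, an asymmetry of the ratio scale that
is documented rather than adjusted away.

## The synthetic cohort

The generator exists because the screening data are not public; it defines
the study conditions under which the pipeline is validated.

* **Blocks**: a jittered square grid (default 900 blocks over a 6-mile
  square), with expected counts mixing a uniform background (15%) and
  Gaussian clusters (default 6, SD 0.6 mi), Poisson-realized, expected
  total 360,000 — producing participant-weighted exposure surfaces with
  mean ≈ 20,000 and SD ≈ 10,000 persons/mi² at the 0.25-mile bandwidth,
  the order of magnitude of a dense urban cohort.
* **Participants** (default 1822): residence at a count-weighted random
  block centroid plus 0.02-mi jitter; covariates drawn independently from
  the study sample's marginals (72.7% female, 57.2% Hispanic, ...); age
  truncated-normal (mean 73.48, SD 10.07, range 50–105).
* **Outcomes**: dentition drawn by inverting the adjacent-categories model
  at true coefficients (defaults follow the magnitudes of the published
  0.25-mile model; the per-unit density effect is set so one SD of
  synthetic exposure gives an OR near 0.87); the missing-tooth count is
  then drawn uniformly within the category's range, since only the category
  is model-determined. Self-rating is drawn from the true logistic model
  and expanded to four levels (poor if 0, else uniform over
  fair/good/excellent).
* **Missingness**: per-variable rates default to the study's observed rates;
  the indicator follows a logistic model in centred age decile and gender
  (coefficients 0.3) with the intercept calibrated by root-finding so the
  marginal rate matches. Age and gender themselves are masked completely at
  random, and a mechanism predictor that is itself masked contributes its
  centred mean — confining any departure from exact MAR to the ~1–2% of
  records affected. A property test confirms that, over 200 replicates,
  missingness shows no dependence on the masked value given the mechanism's
  predictors.

What the generator does **not** emulate: spatial autocorrelation of
covariates, household or network structure, informative (MNAR) missingness,
and measurement error in geocoding. Passing tests therefore demonstrate
correctness of the estimation machinery under MAR with independent
covariates, not robustness to those features of real data.

## Validation sizes and numerical settings

The test suite validates parameter recovery on one complete cohort of
n = 20,000 (every true coefficient within 3 estimated SEs) and interval
calibration on 200 replicates of n = 2,000 with the study missingness rates
and m = 10, requiring ≥ 85% empirical coverage of nominal 95% intervals per
coefficient — the slack acknowledging the asymptotic-normal posterior
approximations in the categorical imputation models. The replicated
coverage study uses 5 chained sweeps per dataset (the package default is
10): with mostly monotone MAR missingness the chains stabilize within the
first few sweeps, and the study size keeps the full validation suite
fast on a single CPU. Tolerances elsewhere: Newton gradient norm
$10^{-8}$; oracle agreement $10^{-5}$ per coefficient; kernel mass
conservation 0.5% at grid step $h/50$.

## Known limitations

* No boundary correction of the density surface; exposures for residences
  near the study-region edge are biased downward.
* Euclidean planar distance only — no street-network or geodesic distances;
  inputs must be pre-projected to miles.
* The imputation posteriors for the logistic and polytomous models are
  asymptotic approximations, not exact Bayes; coverage slightly below
  nominal is expected and is bounded in the tests.
* The per-SD scaling of exposure effects uses the sample SD of the cohort
  at hand, so per-SD magnitudes are not transportable across regions with
  different exposure dispersion.
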