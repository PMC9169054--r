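---
title: "Residential segregation and racial inequities in self-rated health: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residential segregation and racial inequities in self-rated health: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

`seghealth` implements an analysis pipeline for a recurring question in
social epidemiology: do racial inequities in health depend on how
residentially segregated a city is? The outcome is binary fair/poor
self-rated health (SRH); the exposure of interest is self-declared race
(White, Brown, Black, with White as reference); the candidate effect
modifier is city-level residential segregation measured on two dimensions,
household income and race. The package provides every stage — segregation
measurement, city context construction, multilevel modelling, marginal
standardization — plus a synthetic-data generator with known ground truth so
the chain can be validated end to end without restricted census or survey
microdata.

## Segregation: the dissimilarity index

For each city, segregation is the index of dissimilarity over census
tracts,

$$D = \tfrac{1}{2} \sum_{i=1}^{n} \left| \frac{a_i}{A_T} - \frac{b_i}{B_T} \right|,$$

where $a_i$ and $b_i$ count the two comparison groups in tract $i$ and
$A_T$, $B_T$ are their city totals. For the income dimension the groups are
households at or below versus above 2 minimum wages; for the race dimension
Black+Brown versus White residents. $D$ is 0 when both groups are spread
identically over tracts and 1 when they occupy disjoint tracts, and reads as
the fraction of either group that would have to move to equalize the
distributions. The implementation works on raw counts (inputs given as
percentages must be converted upstream), treats empty tracts as contributing
zero, and is exactly symmetric in the two groups.

Cities are classified into tertiles of $D$ per dimension. The customary
"low/medium/high" split is implemented as a rank-based partition into
contiguous thirds with sizes `diff(floor(n * (0:3) / 3))` and ties broken by
city identifier — a deterministic rule, recorded together with the observed
index range per tertile. (How tied index values should be cut is genuinely
underdetermined in the field's usual description; any fixed rule works, but
it must be deterministic for reproducibility.)

## City social environment

Four city-level percentages — adults 25+ with at least primary education,
households with piped water, households with sewage connection, households
with more than 3 people per room — are z-scored across cities (sample SD,
$n-1$), the crowding z-score is negated, and the composite is the mean of
the four. Whether such a composite should sum or average the z-scores only
changes its scale, not city ranks or model fit (coefficients rescale); the
mean keeps the index on an interpretable z-score scale. The composite has
mean zero across cities by construction, and higher values mean a better
social environment.

## The multilevel model

The outcome model is a logistic regression with a city random intercept:

$$\mathrm{logit}\, \Pr(y_{ic} = 1 \mid x_{ic}, b_c) = x_{ic}^\top \beta + b_c,
\qquad b_c \sim N(0, \sigma_b^2).$$

The model ladder mirrors standard practice: model 1 adjusts race for age and
gender; model 2 adds education (4 levels, university reference); model 3
adds the city social-environment composite; models 4A/4B add income/racial
segregation tertiles; models 5A/5B add race-by-tertile interactions. Age
enters linearly in years, centered at 43 (roughly the adult survey mean) so
the intercept refers to a typical respondent. Reference levels are fixed
throughout: White, male, university, low tertile.

Estimation maximizes the marginal likelihood, integrating each city's
contribution over $b_c$ by *adaptive* Gauss–Hermite quadrature: per city the
integrand's mode is located by Newton steps and the quadrature rule is
recentered and rescaled there. The default is 12 nodes; because the rule is
adaptive, estimates are stable to far fewer nodes than a non-adaptive rule
would need, and the test suite checks that doubling the node count moves
coefficients by less than $10^{-4}$. Optimization is quasi-Newton (BFGS)
over $(\beta, \log \sigma_b)$ — the log scale enforces $\sigma_b > 0$ —
started from an ordinary logistic fit with $\sigma_b$ initialized at 0.1,
followed by Newton polishing on the quadrature score until the gradient is
numerically zero. When the likelihood maximizes at the boundary
$\sigma_b \to 0$ the model is the ordinary logistic regression and is
reported as such (`sigma_zero = TRUE`).

Uncertainty uses a city-level cluster-robust sandwich: the per-city scores
of the *marginal* (integrated) log-likelihood, computed by the same
quadrature rule, form the meat (centered, with a $G/(G-1)$ factor), and the
observed information (numerical derivative of the analytic score) forms the
bread. The covariance covers the joint vector $(\beta, \log \sigma_b)$, so
downstream simulation-based intervals can propagate uncertainty in the
random-intercept SD as well. With 27 cities the robust covariance is
estimated from few clusters; no small-sample degrees-of-freedom correction
is applied to confidence intervals (plain 95% intervals are reported), but
the joint interaction Wald statistic is referred to $F(q, G-1)$ via $W/q$,
the standard few-cluster reference, rather than to $\chi^2_q$ which is
anti-conservative at this cluster count.

An independent implementation of the same model (`lme4::glmer` with
adaptive quadrature) is used in the test suite as a cross-check oracle; the
two agree to about $10^{-4}$ on the log-odds scale.

## Marginal standardization

Prevalence ratios and differences are population-level contrasts, not
conditional odds ratios. For a fitted model, the standardized prevalence
under race level $r$ (and optionally segregation tertile $t$) sets that
exposure counterfactually for *every* person in the full analysis sample,
keeps all other covariates (and each person's city) at observed values, and
averages the population-averaged probability

$$\bar p_i = \int \mathrm{logit}^{-1}(x_i^\top \beta + b) \,
  \varphi(b; 0, \hat\sigma_b^2)\, db$$

over persons (quadrature again; a config switch predicts at $b = 0$ instead
for comparison — the population-averaged version is the default because PRs
and PDs are marginal quantities). Then
$\mathrm{PR} = \bar p(\text{comparison}) / \bar p(\text{White})$ and
$\mathrm{PD} = \bar p(\text{comparison}) - \bar p(\text{White})$, overall or
within tertile strata; by construction
$\mathrm{PD} = \bar p_{\mathrm{ref}} (\mathrm{PR} - 1)$ exactly. The
standardization population is always the full sample, including for
stratum-specific contrasts.

Confidence intervals are simulation-based: parameter vectors are drawn from
the asymptotic sampling distribution centered at
$(\hat\beta, \log \hat\sigma_b)$ with covariance $\hat V_{\text{robust}}$,
every standardized quantity is recomputed per draw, and 2.5/97.5 percentiles
are reported. The draws use a multivariate $t$ with $G-1$ degrees of freedom
rather than a normal: with the robust covariance estimated from 27 city
clusters, normal draws are measurably anti-conservative, and the $t$ draw is
the simulation analogue of using $t_{G-1}$ instead of normal critical
values. This handles arbitrary nonlinear functionals without delta-method
derivations and is exactly reproducible — the seed and draw count are
recorded in every output row. Draws below 100 are refused (percentile
instability); the default is 1,000 and results in the package's tests use
150–5,000 depending on the precision needed. The choice of simulation
rather than delta method or bootstrap affects interval width only slightly
and never the point estimates.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, at configurable
scale:

* **Cities and tracts.** 27 cities, each with 40–200 census tracts of
  250–350 households. Tract-level group shares come from a two-parameter
  concentration family: mean share $\rho_c$ and a coupling knob
  $\kappa \in [0,1]$, mapped to a Beta distribution with total concentration
  $8(1-\kappa)/\kappa$. $\kappa = 0$ gives every tract the same expected
  composition (and, at the degenerate knob, deterministic counts, so $D
  \approx 0$); $\kappa = 1$ gives single-group tracts ($D = 1$); in between
  $D$ increases monotonically in $\kappa$. Each city's effective coupling is
  $\kappa^{g_c}$ with $g_c \sim U(0.5, 2)$, spreading index values across
  cities so tertiles are meaningful. Defaults ($\kappa$ = 0.66 income, 0.45
  race) were calibrated once so mean indices are near 0.32 and 0.25; income
  tract shares are mildly blended with race shares (weight 0.15 on the
  logit scale), producing a small cross-dimension correlation.
* **City indicators** are drawn correlated with the realized segregation
  indices so more segregated cities get better social-environment scores,
  reproducing the counter-intuitive context pattern typical of large
  capitals.
* **Persons.** Respondent counts per city are log-normal within 641–3,439
  (median near the geometric midpoint ≈ 1,485); race follows each city's
  census composition, recentered (size-weighted) so the study-wide mix hits
  41.6/48.2/10.2% White/Brown/Black; ages are truncated normal
  (mean 43, SD 16.5, range 18–100); education comes from a cumulative-probit
  latent score depending on race and city context — this builds in the
  race–education confounding that makes education adjustment attenuate race
  contrasts, as in real data; household income tertiles (61.9% observed,
  missing completely at random) follow education and context.
* **Outcome.** Bernoulli from the logistic model with defaults: race
  log-odds 0.18 (Brown) and 0.30 (Black), age 0.025/year, female 0.25,
  education 0.30/0.55/0.85, social environment −0.20, tertile 0.10/0.20,
  race-by-tertile interactions 0.08–0.25 widening the gaps at high
  segregation, $\sigma_b = 0.3$, and an intercept (−1.76) calibrated once by
  simulation so overall prevalence is 31.5%. City intercepts are drawn
  sum-to-zero with exact sample SD $\sigma_b$ — with only 27 cities this
  keeps the intercept and marginal prevalence identifiable in recovery
  studies without changing the model being fitted.

`true_marginals()` is the generative oracle: it simulates a large covariate
population (fresh cities, ~10^6 persons by default), applies the *known*
generating coefficients under counterfactual race/tertile assignment, and
integrates over the random-intercept distribution, yielding the exact
standardized prevalences, PRs and PDs that the estimation pipeline should
recover.

What the generator does **not** emulate: the survey's complex sampling
design (strata, PSUs, weights — the analysis deliberately uses none), the
real joint covariate distribution, spatial adjacency of tracts, or
within-city neighbourhood-scale segregation. Passing tests therefore show
that the estimators recover the estimands under the assumed data-generating
structure, not that the substantive findings hold in any particular real
population.

## Numerical and design choices

* Quadrature: 12 adaptive nodes by default, exposed as `nodes` everywhere.
* Convergence: BFGS relative tolerance $10^{-10}$, then Newton polish to
  score $< 10^{-4}$; a fit whose final score norm exceeds 0.1 is flagged
  `converged = FALSE` and refused by the standardization layer.
* Boundary: $\hat\sigma_b < 10^{-3}$ is treated as 0 (ordinary logistic
  regression; cluster sandwich over $\beta$ only).
* Tertile ties: stable sort by city id; floor rule for non-divisible city
  counts (sizes differ by at most one, extras to the upper tertiles).
* Education stratification in sensitivity analyses is dichotomized
  university+secondary versus primary+less-than-primary (configurable);
  income sensitivity uses complete cases only, no imputation.
* Degenerate inputs error early and descriptively: zero group totals name
  the city and group; rank-deficient designs name the aliased columns;
  strata with fewer than 2 cities or a degenerate outcome are skipped with
  a warning.

## Validation problem sizes

The test suite validates the chain at sizes chosen to run comfortably on a
single CPU: oracle equivalence of the dissimilarity index on 200 random
tract tables; degenerate-model equivalence against `glm` at ~55,000 persons;
coefficient recovery over 40 replicates of ~13,500 persons in 27 cities
(mean absolute bias below 0.02 log-odds); stratified-PR ordering recovery
over 40 replicates of ~20,000 persons under a strong generating interaction
(0.9 log-odds Black-by-high-tertile, set well above the stratified
estimator's ~0.2 sampling SD so monotone ordering is the expected outcome);
interval calibration over 100 replicates (coverage required in 90–99%); and
null calibration of the interaction test over 100 replicates (rejection
count within the exact binomial 95% region around 5%). Larger
sizes tighten the Monte-Carlo error but do not change any conclusion.

## Known limitations

* City-level inference rests on 27 clusters; robust variance estimates are
  noisy at that count and confidence intervals carry no small-sample
  correction.
* The model sequence treats education as a confounder-style covariate; in a
  structural-racism framing it is better viewed as a mediator, so
  education-adjusted race contrasts are conservative.
* Only one random intercept (city) is supported — no survey weights, no
  crossed or nested random effects, no Bayesian estimation.
* Segregation is measured at whole-city scale; neighbourhood-scale exposure
  is out of scope.
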