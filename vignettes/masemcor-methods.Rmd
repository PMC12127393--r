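---
title: "Meta-analytic pooling and mediation of correlations: models, choices, limits"
author: "masemcor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic pooling and mediation of correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masemcor)
```

# The problem

A sizeable cross-sectional literature correlates physical activity (PA) with
mobile-phone addiction (MPA) in adolescents and young adults, and a subset of
those studies also measures self-control (SC) as a putative mediator. Each
primary study contributes up to three Pearson correlations — r(PA,MPA),
r(PA,SC), r(SC,MPA) — at its own sample size, and most studies report only
the first. `masemcor` implements the full inference pipeline for this kind of
evidence base: random-effects pooling per correlation, heterogeneity and
publication-bias diagnostics, categorical moderator contrasts, and a
two-stage meta-analytic structural equation model (MASEM) that asks how much
of the PA–MPA association runs through self-control.

# Models and estimators

## Fisher-z pooling

Every correlation is mapped to the variance-stabilizing scale
$z = \tfrac12\log\frac{1+r}{1-r}$ with sampling variance $V_z = 1/(n-3)$.
Pooling is inverse-variance weighted on the z scale; the point estimate and
the confidence-interval endpoints (not the variance) are back-transformed
with $r = \tanh(z)$. The random-effects model adds a between-study variance
$\tau^2$, estimated by DerSimonian–Laird,
$\hat\tau^2 = \max\!\big(0,\,(Q - df)/C\big)$ with
$C = \sum w - \sum w^2 / \sum w$, and weights $1/(V_z + \tau^2)$.
Heterogeneity is summarized by Cochran's $Q$ (computed at the fixed-effect
stage) and $I^2 = \max(0, (Q - df)/Q)$, with $I^2 > 75\%$ conventionally
read as high. Inference for the pooled effect uses the normal distribution.

DerSimonian–Laird and normal (rather than Knapp–Hartung) inference are
deliberate: they are the defaults of the mainstream commercial software used
for analyses of this literature, so results are directly comparable.
REML-type estimators could be added behind the same interface. A known
limitation is that DL with normal inference is mildly anticonservative when
$k$ is small and $\tau^2$ large.

## Publication-bias diagnostics

* **Egger regression** — unweighted OLS of the standardized effect
  $z_i/SE_i$ on precision $1/SE_i$; the intercept's two-tailed $t$ test on
  $k-2$ df. Identical standard errors make the design singular and are
  refused rather than silently dropped.
* **Rosenthal fail-safe N** — the smallest integer $N$ of hidden null
  studies such that $|\sum Z_i|/\sqrt{k+N}$ falls below the critical value
  ($z_{crit} = 1.96$ two-tailed at $\alpha = .05$ by default; one-tailed
  1.645 available). The robustness flag uses Rosenthal's $5k+10$ rule. The
  two-tailed default mirrors the configuration of the software environment
  this package mirrors; the ceiling-style integer rule is the smallest N
  that *strictly* kills significance, which keeps the defining inequality
  testable at the boundary.
* **Trim-and-fill** — Duval–Tweedie with the $L_0$ estimator, fixed-effect
  centering during iteration and random-effects pooling of observed plus
  imputed studies at the end. Ties in the absolute deviations are midranked,
  and near-ties (within floating-point noise) are treated as exact ties so
  the estimator is exactly zero on symmetric fixtures. The `side` argument
  names the *heavy* (trimmed) side; `side = "auto"` picks the side with the
  larger one-sided rank sum of deviations from the fixed-effect center.
  Convergence means the same $L_0$ twice; after 20 iterations the function
  aborts with diagnostics rather than returning a non-converged adjustment.

## Subgroup moderation

Within each moderator level, random-effects pooling as above, each level
with its own $\tau^2$ by default ("do not pool within-group variance");
`tau2 = "common"` shares one DL estimate across levels. Between levels the
fixed-effect statistic
$Q_B = \sum_j w_j(\hat\theta_j - \bar\theta)^2$, $w_j = 1/SE_j^2$, is
referred to $\chi^2_{G-1}$. Levels contributing a single study cannot
support a within-level random-effects fit; they are excluded with a warning
instead of failing the whole analysis.

## Two-stage MASEM

**Stage 1** pools each correlation cell univariately over the studies that
report it and assembles the symmetric 3×3 matrix, verifying positive
definiteness (a non-PD pooled matrix is an error carrying the offending
eigenvalue — it is never silently bent). This is a transparent,
oracle-testable approximation to multivariate TSSEM; because the pooled
matrix is an explicit interface object, a multivariate GLS stage 1 could be
slotted in without touching stage 2. The effective sample size defaults to
the sum of the complete-reporting studies' $n$ (a harmonic-mean rule and an
explicit override are available; the override is what you use when
reproducing a published analysis that reports its own effective n).

**Stage 2** fits the saturated standardized path system
$$SC = a\,PA + e_1, \qquad MPA = c\,PA + b\,SC + e_2$$
in closed form: $a = r_{PA,SC}$ and $(c, b)$ solve the 2×2 normal equations
of the two-predictor regression. The indirect effect is $ab$, the total
effect $d = c + ab$ equals $r_{PA,MPA}$ identically, and the proportion
mediated $ab/d$ is reported only for consistent mediation (same signs);
inconsistent mediation yields an explanatory code, not a number. With zero
degrees of freedom the model reproduces the input matrix exactly, so fit
indices are trivially perfect and are reported as such.

Wald standard errors use standardized-OLS asymptotics at the effective
sample size: $SE(a)^2 = (1-a^2)/(n-2)$ and
$\mathrm{Var}(c,b) = (1-R^2)\,S^{-1}/(n-3)$ with $S$ the predictor
correlation block. The Monte-Carlo interval for $ab$ draws $(a^*, b^*)$ from
independent normals and takes equal-tail quantiles of the product — the
product distribution is skewed, so this is preferable to a symmetric Sobel
interval. These are approximations to (unstated) likelihood-based intervals
a full MASEM engine would produce; published intervals should be treated as
sanity envelopes rather than exact targets, and the univariate stage 1
understates between-cell dependence, so stage-2 intervals are, if anything,
slightly narrow.

# The synthetic generator

`simulate_studies()` draws, per study: a sample size (lognormal between the
range endpoints, median at the geometric mid-range); study-true Fisher-z
values as population z plus $N(0, \tau_z)$ per cell; and then an actual
trivariate normal sample of that size from the study-true matrix, whose
sample correlations become the observed effects. Drawing raw data — rather
than adding independent noise per cell — guarantees each study's three
correlations are mutually consistent (jointly positive definite), which
independent per-cell perturbation does not. The missing-cell pattern keeps
all three correlations only for `k_complete` studies; the rest report only
r(PA,MPA).

Default configuration, chosen once to emulate the shape of the adolescent
PA/SC/MPA literature: 48 studies, 10 complete, $n \in [86, 9569]$,
population paths $(a, b, c) = (0.213, -0.429, -0.092)$ (so the implied
population correlations are $r_{PA,SC}=0.213$, $r_{PA,MPA}=-0.183$,
$r_{SC,MPA}=-0.449$), a secondary-school share of 20% whose PA–MPA
association is weakened by $+0.08$ on the z scale (the educational-stage
moderation the subgroup machinery must detect), and $\tau_z = 0.02$ —
moderate heterogeneity ($I^2 \approx 30\%$ at $n \approx 1000$), the regime
in which end-to-end parameter recovery is a sharp test of estimator
correctness. The real literature is far more heterogeneous
($I^2 > 95\%$, implying $\tau_z \approx 0.25$); that regime is reachable via
`tau_z` and is useful for stress tests, but under it a 10-study mediation
subset cannot pin paths to ±0.05 by any estimator, so it would make recovery
tests uninformative about correctness. What passing recovery tests show is
that the estimators are right, not that 10 real studies determine the
mediation paths tightly.

## The censoring demonstration

`apply_censoring()` implements a one-sided file drawer: studies whose
standard-normal score lies on the chosen side of zero with $|Z_i|$ below a
threshold are dropped with a given probability. Two analytical facts shaped
the documented demonstration scenario (`bias_demo_config()`):

* Suppressing a *significance window* ($|Z_i| < 1.96$ on one side) removes a
  band whose width on the effect scale is proportional to $SE_i$; that
  shifts the Egger *slope*, not the intercept, and is nearly invisible to
  the test (detection rates under 20% in pilot simulations).
* Suppressing by *sign* removes a fraction of studies that depends on
  $\Phi(-|\mu|/\sigma_n)$, which varies with $n$ only through the sampling
  part of $\sigma_n$ — so the induced small-study asymmetry is strong
  exactly when the true effect is weak, heterogeneity is small, and many
  studies are small.

The demonstration therefore uses a weak-effect, small-study literature:
population $r_{PA,MPA} = -0.05$, $\tau_z = 0.005$, 60 studies with
$n \in [10, 2000]$, and every wrong-sign (positive) result unpublished —
about a third of the literature. Under that scenario Egger's test is
significant and trim-and-fill imputes at least one study in well over 80% of
replicates. Conversely, at the sample sizes of the real PA/MPA literature
(hundreds to thousands per study, almost every result significant), sign-
or significance-based selection leaves almost no detectable funnel
signature — which is worth remembering when a clean funnel plot is offered
as evidence of no bias.

# Numerical and coding choices

* Correlations within $10^{-12}$ of $\pm 1$ are rejected everywhere, never
  clamped: that close to unity they are almost certainly data errors.
* Multi-dimensional instruments are collapsed by the arithmetic mean of the
  reported raw correlations (not the z-scale mean): that is the plain
  reading of the usual coding rule, and the difference is negligible for
  $|r| < 0.6$.
* Duplicate samples are resolved to the earliest publication, ties broken
  lexicographically by study id, and only via an explicit duplicate-group
  column — no fuzzy auto-detection.
* The fail-safe integer is `floor(val) + 1` rather than `ceiling(val)`:
  identical except when `val` is an exact integer, where the ceiling would
  leave the combined score exactly *at* the critical value instead of
  strictly below it.
* Trim-and-fill ranks are midranks, and deviations equal up to
  floating-point noise are forced into exact ties before ranking, so
  symmetric fixtures give $L_0 = 0$ exactly.
* Imputed-study sample sizes are recovered from their variances via
  $n = 3 + 1/V_z$, which is exact for Fisher-z effects.

# A worked example

The pooled matrix reported for this literature (bundled as a JSON fixture)
feeds stage 2 directly:

```{r worked}
m <- read_pooled_matrix(system.file("extdata", "pooled_pa_sc_mpa.json",
                                    package = "masemcor"))
fit <- stage2_fit_mediation(m)
summary(fit)
indirect_ci_montecarlo(fit, seed = 1)
```

And the synthetic pipeline end to end:

```{r pipeline}
st <- simulate_studies(sim_config(), seed = 7)
pool_pair(st, "pa_mpa")
fit2 <- stage2_fit_mediation(stage1_pool_matrix(st))
coef(fit2)
```

# Validation design and problem sizes

Every estimator is tested two ways: against hand-computed fixtures frozen
from independent closed forms (direct-summation pooling oracle, closed-form
OLS for Egger, manual $L_0$ iteration, the 2×2 solve for stage 2, a
numerical discrepancy minimizer for the path model), and against seeded
simulations (200 replicates of the default 48-study shape for end-to-end
path recovery; 500 replicates of the censoring demonstration for
bias-diagnostic power; 200 replicates for pooled-effect bias and CI
coverage). `metafor` serves as an additional independent cross-check for DL
pooling and the $L_0$ estimator, never as the implementation. These problem
sizes keep the whole suite under a minute on a single core while leaving
the Monte-Carlo margins of the pass thresholds comfortably wide.

# Known limitations

* Univariate stage-1 pooling ignores the sampling covariance between cells
  from complete studies (a full TSSEM would not).
* No Knapp–Hartung small-sample adjustment; no REML/PM $\tau^2$ estimators
  yet (the estimator enum is the extension point).
* No effect-size conversions from d, OR or t; inputs must be correlations.
* No selection-model corrections (PET-PEESE, Copas, p-uniform) — trim-and-
  fill is kept because it is the field's reporting convention, not because
  it is the strongest available adjustment.
* Dependent effect sizes within a study (multiple scales, multiple
  subsamples) are out of scope; the coding rules collapse them first.
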