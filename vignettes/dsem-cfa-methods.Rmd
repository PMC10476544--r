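---
title: "Two-level dynamic factor analysis: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level dynamic factor analysis: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dsemcfa` fits a one-factor, two-level dynamic confirmatory factor model to
intensive longitudinal item panels: persons $i = 1,\dots,N$ answer $K$
items (seven for a DASS-21 subscale) at sessions $t = 1,\dots,T_i$. Each
observed response decomposes into a person-specific mean and an
occasion-specific deviation,

$$y_{itk} = \underbrace{\nu_k + \lambda^{(b)}_k\,\eta^{(b)}_i +
\varepsilon^{(b)}_{ik}}_{\text{between: } m_{ik}} +
\underbrace{\lambda^{(w)}_k\,\eta^{(w)}_{it} +
\varepsilon^{(w)}_{itk}}_{\text{within}},$$

with diagonal residual covariances at both levels
($\varepsilon^{(b)}_{ik} \sim N(0, \theta^{(b)}_k)$ drawn once per
person-item, $\varepsilon^{(w)}_{itk} \sim N(0, \theta^{(w)}_k)$ per
occasion). The within-level factor follows a person-specific AR(1),

$$\eta^{(w)}_{it} = \phi_i\,\eta^{(w)}_{i,t-1} + \zeta_{it},\qquad
\zeta_{it} \sim N(0, \sigma^2_{\zeta,i}),$$

initialized at its stationary distribution
$N\!\big(0, \sigma^2_{\zeta,i}/(1-\phi_i^2)\big)$. The triple
$u_i = \big(\eta^{(b)}_i,\ \phi_i,\ \log\sigma^2_{\zeta,i}\big)$ is a
person-level random effect, $u_i \sim \mathrm{MVN}(\gamma + B x_i,
\Sigma_b)$, so carryover and (log) innovation variance vary across persons
and covary with the trait factor. Covariates $x_i$ (for example a
male dummy) enter only at the between level.

**Identification.** One anchor item's unstandardized loading is fixed to 1
at both levels, which puts the two levels on a common scale and makes the
cross-level loading difference $\lambda^{(b)}_k - \lambda^{(w)}_k$
interpretable. All item intercepts $\nu_k$ are free, so the grand mean of
the trait factor is fixed to zero; in the conditional model the covariate
effect on $\eta^{(b)}$ is then identified against the reference-group mean
of zero, and the reported `gamma` rows are reference-group means.

**Time.** Session indices are compressed to consecutive occasions: the
model treats retained rows as adjacent measurements (the lag-1 carryover is
"session-to-session"), and calendar spacing is ignored. Rows whose items
are all missing carry no information and are dropped; a mid-series skipped
session therefore shortens the series rather than inserting a latent
occasion. Individually varying continuous-time lags are out of scope.

## Priors

Proper but very diffuse defaults (`default_priors()`): normal$(0, 10^6)$
for loadings, intercepts and fixed effects; inverse-gamma$(0.001, 0.001)$
for residual variances; inverse-Wishart with identity scale and 5 degrees
of freedom (dimension + 2, so the prior mean of $\Sigma_b$ equals the
scale) for the random-effect covariance. Propriety guarantees a
well-defined posterior; with these settings the data dominate all
well-identified parameters. One caveat worth knowing: when a true
random-effect variance is far below the identity scale (for example a
carryover variance of 0.07), the inverse-Wishart scale contributes a mild
upward pull at small $N$; sensitivity checks with oracle-scaled and
near-flat alternatives showed this does not drive the recovery behavior
discussed below.

## Estimation

`run_mcmc()` runs two (or more) Gibbs chains, each a deterministic
function of the seed. Update blocks per sweep:

1. **Person dynamics $(\phi_i, \log\sigma^2_{\zeta,i})$** — joint
   random-walk Metropolis against the *marginal* within likelihood: the
   latent states are integrated out by a sequential linear-Gaussian
   (Kalman) filter with stationary initialization, missing cells skipped
   in the observation update. The proposal scale adapts per person during
   burn-in only and is frozen afterwards, preserving detailed balance on
   the retained half. Proposals with $|\phi| \ge 0.999$ are rejected
   (stationarity region), which truncates the posterior at the unit root.
2. **Latent states** — forward filtering, backward sampling.
3. **Level interweaving** — an exact Gibbs draw along the direction
   $m_{ik} \mapsto m_{ik} + \lambda^{(w)}_k c_i$,
   $\eta^{(w)}_{it} \mapsto \eta^{(w)}_{it} - c_i$: the within likelihood
   is invariant along it, and $c_i$ has a closed-form normal conditional
   from the between prior of $m_{ik}$ and the AR prior of the shifted
   states. Without this move the split between person-item means and the
   state level mixes extremely slowly for short series with high
   carryover.
4. **Person-item means, trait scores** — conjugate normal draws.
5. **Measurement parameters** — conjugate normal (loadings, intercepts)
   and inverse-gamma (residual variances) draws; anchor loadings pinned.
6. **Fixed effects and $\Sigma_b$** — conjugate multivariate normal and
   inverse-Wishart draws.

The first half of each chain is burn-in. Convergence is controlled by the
potential scale reduction computed on the retained halves,
$\mathrm{PSR} = \sqrt{(W + B)/W}$ with $W$ the mean within-chain variance
and $B$ the between-chain variance of chain means; identical chains give
exactly 1. `converge_and_rerun()` doubles the iteration count until all
monitored parameters fall below the threshold (default 1.05, a common
strict criterion), then re-runs once at `rerun_multiplier` (3 by default,
in $[3,4]$) times the converged count to guard against premature
stoppage; an exhausted budget or a failed re-run returns a
convergence-failure flag, never a silent success. Posterior summaries are
medians with equal-tailed 95% credible intervals. Derived quantities —
loading differences and ratios, random-effect correlations, the
person-average stationary within variance — are computed per retained
draw and summarized afterwards, never from summarized marginals.

**Correctness checks behind the implementation.** The Metropolis block
was validated against an exact two-dimensional grid posterior for a
single person; the backward-sampling block against the exact Kalman
smoother (including missing cells); all blocks jointly by Geweke
successive-conditional simulation under informative priors (including
series as short as $T = 2$); and the full posterior against an
independent implementation of the identical model in JAGS on shared
data, which reproduced all parameter summaries closely.

## Psychometric outputs

Per retained draw, item $k$'s between-level variance is
$\lambda^{(b)2}_k \Sigma_{b,11} + \theta^{(b)}_k$ and its within-level
variance $\lambda^{(w)2}_k \bar V_w + \theta^{(w)}_k$, where $\bar V_w$
is the person-average stationary latent variance
$\tfrac1N\sum_i \sigma^2_{\zeta,i}/(1-\phi_i^2)$ computed from that
draw's person-specific effects. The ICC is the between share of the
total; the level-specific $R^2$ is each level's common-factor share.
Averaging over the sampled persons (rather than plugging in fixed
effects) respects random-effect heterogeneity; a fixed-effects-only mode
(`mode = "fixed"`, using $\exp(\gamma_v + \Sigma_{b,33}/2)$ and
$\gamma_\phi$) is provided for comparison. A caution that matters for
simulation work: with normally distributed carryover truncated at
$|\phi| < 1$, the population mean of $\sigma^2/(1-\phi^2)$ diverges
logarithmically, so $\bar V_w$ is defined over realized persons, is
heavy-tailed across samples, and can be dominated by a handful of
near-unit-root persons. `true_psychometrics()` therefore takes the
realized random effects when evaluating a simulation truth.

An item is flagged noninvariant when the 95% interval of its per-draw
loading difference excludes zero — exactly the measurement table's
bolding rule; no multiplicity correction is applied (mirroring common
practice in applied reporting), which the per-item type-I calibration
test quantifies. Anchor selection (`select_anchor()`) adapts the triangle
heuristic operationally: a provisional fit with a reference item, per-draw
cross-level loading *ratios* $r_k = \lambda^{(b)}_k/\lambda^{(w)}_k$
(scale-free, hence insensitive to the provisional reference), pairwise
95% interval tests of $r_j - r_k$, and an exhaustive maximum-clique
search of the mutual-invariance graph ($K \le 10$ keeps this trivial);
ties break toward the highest within-level reliability. No clique of
size two or more is an error, not a silent fallback.

## The synthetic-data generator

`simulate_panel()` draws from the exact generative process above, and its
defaults emulate a realistic clinic sample: $N = 333$ persons,
series lengths from a shifted negative binomial with mean 10.76, SD 6.3
and a floor of 2 sessions, seven items per factor, and a structural block
(`default_true_params()`) taken from the published unconditional estimates
for the depression subscale: carryover mean 0.454 and variance 0.072, log
innovation-variance mean $-3.263$ and variance 2.350, trait variance
0.247, and random-effect correlations $(0.704, 0.647, 0.255)$. Loadings
follow the published per-item values; residual variances are derived from
the published level-specific $R^2$ targets through the plug-in within
variance $\exp(\gamma_v + \Sigma_{33}/2)/(1 - \gamma_\phi^2 -
\Sigma_{22})$, so typical panels land in realistic ICC and reliability
ranges. A stress-style profile and a gender-conditional variant (male
dummy with rate 0.357, a typical clinic sample's share of men; effects $-0.15$, $-0.10$,
$-0.24$ on trait, carryover and log innovation variance) are included.
These fixtures are defaults informed by published estimates, intended
for simulation studies; they are not ground truth. Carryover draws outside $(-1, 1)$ are rejected and the
triple redrawn (count recorded), matching the stationary estimation
model; responses are kept continuous by default, with an optional
clamp-and-round mode for realism studies. Missingness is MCAR only — the
study's real missingness was informative, and no mechanism is available
to emulate it, so recovery results here do not speak to MNAR robustness.

## What the simulation studies show — and their limits

With measurement of typical reliability, the structural block is
recovered well when series are moderately long (at $T = 25$ the carryover
mean is recovered essentially without bias). Under the emulated sample's own
conditions — median series around ten sessions, many as short as two,
and enormous innovation-variance heterogeneity
($\mathrm{Var}(\log\sigma^2_\zeta) = 2.35$ means a middle 68% range of
person innovation variances spanning a factor of $e^{3}$) — the exact
posterior of the carryover mean sits systematically below the generating
value (median attenuation around $0.1$ at $N = 100$, $T = 11$), and the
trait-carryover correlation is similarly compressed. This is not a
sampler artifact: the independent JAGS implementation produces the same
posterior, and the effect shrinks as $T$ grows. It is the two-level
analogue of the classic short-series AR bias, surviving hierarchical
pooling because so many persons carry almost no individual carryover
information. Practically: with panels like these, between-level
measurement quantities (ICC, between $R^2$, loading differences,
covariate effects on the trait) are trustworthy, while the absolute
location of the carryover mean and variance should be read with this
attenuation in mind. The acceptance suite reports these recovery numbers
as measured rather than adjusting the conditions to mask them.

Test problem sizes were chosen to keep the full suite fast while leaving
each check informative: oracle comparisons run on toy instances (one
person, $T \le 6$, $K \le 3$); recovery uses 20 replicates at $N = 100$,
$T = 11$; type-I calibration 100 replicates at $N = 40$, $T = 8$; planted
noninvariance 20 replicates at $N = 150$; conditional recovery 10
replicates at $N = 300$; chains of 1,200-4,000 iterations with PSR
monitored. Passing these says the implementation is internally coherent
and recovers its own generative process at those sizes; it does not
certify behavior on ordinal responses (treated as continuous here), under informative missingness, or under
nonstationary trends — therapy data may drift early in treatment, and
the AR(1) model assumes that away.

## Numerical choices and degenerate inputs

Stationary initialization everywhere (simulator, filter, FFBS); the
$|\phi^\*| \ge 0.999$ Metropolis rejection bounds the filter away from the
nonstationary boundary; residual-variance draws are floored at $10^{-12}$;
non-positive-definite $\Sigma_b$ proposals cannot arise (inverse-Wishart
draws are positive-definite by construction) and `joint_logposterior()`
returns $-\infty$ rather than erroring for one; a degenerate all-zero
$\Sigma_b$ is allowed in the simulator only. Items with no observations
fall back to their priors; persons with fewer than two sessions are
excluded at panel construction and recorded. Chains are initialized from
moment estimates with chain-specific over-dispersed jitter.
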