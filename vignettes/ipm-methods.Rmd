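---
title: "Methods: regional integrated population models for a migratory songbird"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional integrated population models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Regional populations of short-lived migratory songbirds can follow opposite
trajectories within one country: stable or increasing in one region,
declining in another. Telling apart the demographic routes to those
trajectories — does survival or productivity drive the divergence? — needs
the abundance trend and the demographic rates estimated *jointly*, because
no single monitoring stream observes all of them. An integrated population
model (IPM) does exactly that: it couples an annual abundance index,
individual nest records and mark–recapture histories in one state-space
likelihood, so that the latent population size, annual adult survival,
the components of productivity and a residual recruitment term are
estimated simultaneously, with uncertainty propagated between streams.

`ipmdemog` implements such a regional IPM end-to-end, together with the
three analyses usually layered on top of it: per-MCMC-draw correlations
between annual growth rates and each demographic rate, a simulated
growth-rate surface over the survival-by-productivity plane, and
counterfactual "what if this region had the other region's rates"
trajectory substitutions. Because the motivating monitoring datasets are
not public, the package ships a synthetic-data generator whose presets are
centred on the published posterior means for the two British regions of
the motivating system; every downstream claim is tested against data with
known truth.

## The population model

The female population in year $t$ comprises surviving adults and recruits,

$$N_t = N_{a,t} + N_{r,t},$$

with stochastic transitions

$$N_{a,t} \sim \mathrm{Binomial}(N_{t-1},\ \varphi_{ad,t-1}), \qquad
  N_{r,t} \sim \mathrm{Poisson}\!\left(N_{t-1}\cdot 0.5\cdot F_{t-1}\cdot \rho_{t-1}\right),$$

where $F$ is productivity (fledglings per breeding attempt, FPBA),
decomposed as

$$F = B\,\varphi_{egg}^{ep}\,\varphi_{yng}^{yp},$$

brood size times daily nest survival through the egg stage ($ep$ days of
incubation) and the chick stage ($yp$ days of brooding). The factor 0.5
keeps only the female half of production (equal sex ratio), and $\rho_t$
is a per-transition scaling factor absorbing everything recruitment-shaped
that the data streams cannot measure: first-year survival, dispersal,
multiple brooding and the fraction of the population breeding. The index
scale is arbitrary, so $N_1$ is anchored at 1000.

The observed index $y_t$ is log-normal around the latent size,

$$\log y_t \sim \mathrm{Normal}(\log N_t,\ \sigma^2).$$

Years with no survey simply contribute no observation term; the process
equations still propagate $N_t$ through the gap, which is how the package
imputes unsurveyed years (the generator masks year 8 of 19 by default to
exercise exactly this path).

### Component likelihoods

* **Counts** — the log-normal observation density above, one term per
  surveyed year; `observation_loglik()`.
* **Mark–recapture** — a Cormack–Jolly–Seber likelihood over encounter
  histories from constant-effort sites, conditioning on first capture,
  with time-varying annual adult survival and a single constant recapture
  probability $p$ (constant effort is what motivates a time-constant
  $p$); `cjs_loglik()`. Unseen tails are marginalised with the usual
  $\chi$ recursion. Inside the sampler the same likelihood enters through
  its sufficient statistics, the m-array, as a product of multinomials;
  the test suite proves the two routes agree (up to data-dependent
  constants) and that both match exhaustive enumeration of latent fates
  on short histories.
* **Nest survival** — a Mayfield-type exposure-day likelihood:
  every survived day-at-risk contributes $\log\varphi$ and a failure
  contributes $\log(1-\varphi)$ on its final day; `nest_loglik()`. The
  package's record convention is that `egg_days`/`chick_days` count total
  exposure days *including* the failure day, which makes "a failure with
  zero exposure days" a contradiction the validators reject, and yields
  the closed-form MLE (survived days)/(total days) exactly.
* **Brood size** — zero-truncated Poisson with a per-season mean, since a
  successful nest has at least one young and the model needs a single
  mean parameter to play the role of $B$; `brood_loglik()`. The rate
  parameterisation means the distribution's mean exceeds the rate by the
  truncation factor $1/(1-e^{-B})$, about 0.3% at $B \approx 5.8$ — the
  generator accounts for this in its own expectation tests.

`joint_loglik()` sums these with the process densities and log priors and
is the reference posterior kernel the tests probe (additivity, support
violations, prior finite differences).

## Priors

All probabilities carry Uniform(0, 1) priors (daily nest survival on the
probability scale), brood mean Uniform(0, 10), and the observation s.d. a
half-Normal(0, 1). The yearly $\rho_t$ are *exchangeable*:

$$\log \rho_t \sim \mathrm{Normal}(\mu_\rho, \sigma_\rho), \qquad
  \mu_\rho \sim \mathrm{Normal}(0, 2), \qquad
  \sigma_\rho \sim \text{half-Normal}(0, 1).$$

This hierarchical form is a deliberate design decision, and the one place
where the package departs from a flat-prior reading. With independent
Uniform(0, 5) priors, the eighteen free $\rho_t$ can interpolate the
counts year by year, which leaves a ridge between $\rho_t$, the latent
$N_t$ around unsurveyed years, and $\sigma$: the observation s.d. is then
only weakly identified and the ridge mixes far too slowly for desk-scale
chains (measured split-$\hat R$ of 2–4 on those parameters). Partial
pooling of $\log\rho_t$ (implemented non-centred, which keeps the
sampler off the funnel where a year's recruitment is weakly informed)
removes the per-year escape valve and identifies $\sigma$, while still
letting $\rho_t$ vary by year. Desk-scale chains then typically converge
cleanly, though the weakly identified corners — $\rho_t$ around an
unsurveyed year and at the ends of the series — can still show
split-$\hat R$ slightly above 1.1 in a minority of replicates; these are
slow modes of the joint ($\rho_t$, latent path) configuration under
single-site updates, and the study-scale configuration is the remedy
when they matter. The flat option remains available
(`default_priors(rho_prior = "uniform")`) for sensitivity analysis at
longer run lengths.

$\sigma$ is a single constant per region: a free yearly $\sigma_t$ is not
identifiable from one count per year, and no yearly observation-error
information exists in this design.

## Sampling and diagnostics

`fit_ipm()` expresses the model in JAGS (via `rjags`) with discrete
latent $N_{a,t}, N_{r,t}$ — the integer support of the process equations
is kept, not approximated — and runs, by default, 4 chains of 20,000
iterations, discarding 10,000 as burn-in (the first 1,000 of which are
the adaptive phase; tuning is frozen afterwards) and thinning by 10:
4,000 retained draws. `study_scale_config()` mirrors the heavier
protocol of the motivating study (10 chains of 200,000, half discarded,
thin 50). The published description of that protocol says it yields
40,000 retained draws while its arithmetic gives 20,000; the package
exposes chains/iterations/thinning as configuration and takes no side.

Chains are initialised at prior mid-range values except daily nest
survival, which starts at 0.9 of its upper bound: passerine daily nest
survival is near 1, and a mid-range start (period survival $0.5^{13}$)
would place the initial Poisson recruitment mean absurdly far into the
tail. Latent states start at the observed counts, log-interpolated
through gaps. Every chain gets its own Mersenne–Twister seed derived
from the configuration seed, so refits are bit-identical.

Convergence is summarised by a split Gelman–Rubin statistic (each chain
halved, classical $\hat R$ over the resulting sequences), floored at 1:
with zero between-sequence variance the ratio estimator dips below 1 by
a factor $(n-1)/n$ that is slack, not signal. The whole-fit flag is
`max` $\hat R < 1.1$, the conventional threshold. Derived quantities are
appended per draw: $F_t$ from its definition and $\lambda_t =
N_{t+1}/N_t$, so that the posterior mean of $\lambda$ is always the mean
of ratios, never a ratio of means.

## Correlation analyses

`growth_rate_correlation()` computes, for every retained draw, the
Pearson correlation across transitions between $\lambda$ and a chosen
demographic rate, then summarises that distribution by its mean, its
0.025/0.975 quantiles and the probability of a positive correlation.
One alignment convention is applied throughout
(`align_transitions()`): $\lambda_t = N_t/N_{t-1}$ is paired with the
rates governing the $t-1 \to t$ transition — survival over that
interval, and the productivity of breeding season $t-1$. A 19-year study
therefore correlates over 18 transitions, and the tests include a
misalignment control showing that shifting the convention by one year
destroys a known lag-0 correlation. Egg- and chick-stage survival enter
on the period scale ($\varphi^{days}$), the scale on which such tables
are conventionally reported; Pearson correlation is the default to match
the linear presentation of such analyses, with rank correlation behind a
flag. Draws in which a rate is constant (undefined correlation) are
dropped and counted separately rather than silently propagated.

`cross_region_correlation()` applies the same machinery across two
independently fitted regions, pairing draws by retained-draw index:
since the fits are independent, any pairing is exchangeable, and index
pairing is reproducible. Unequal draw counts are reconciled by evenly
spaced subsampling of the longer set.

## Growth surface and counterfactual substitutions

`growth_surface()` evaluates expected growth $\lambda = \varphi + 0.5 F
\bar\rho$ over a grid (default 50 × 50) spanning the union of both
regions' posterior-mean yearly (survival, FPBA) ranges, holding $\rho$
at its grand posterior mean over both regions and years. The closed form
is the default because it is exact and exactly monotone in both axes; a
stochastic mode (Monte-Carlo mean of one-step binomial + Poisson
transitions) is retained because the quantity is defined by simulation,
and the tests verify the two agree within Monte-Carlo error cell-wise.

`substitute_trajectory()` re-projects a fitted region from a chosen year
onward with one rate — annual survival or FPBA — taken from a donor
region's paired draw, everything else (including $\rho_t$) from the
target draw, and no density dependence, mirroring the assumption that
other rates do not respond. Two design choices were genuinely open:

* the projection is *stochastic per draw* by default (binomial survivors,
  Poisson recruits), so demographic and parameter uncertainty both
  propagate; a deterministic-expectation mode exists for comparison;
* each draw restarts from *its own* latent $N$ at the substitution year
  (`n_start_rule = "draw"`), keeping within-draw coherence rather than
  collapsing to the posterior mean.

Note that a re-projection — even a self-substitution with the target's
own rates — answers a posterior-*predictive* question: unlike the fitted
trajectory it is not conditioned on the counts after the substitution
year, so its spread is wider than the baseline's by construction. The
identity check in the test suite therefore compares two independently
seeded self-projections, which must be distributionally indistinguishable.
`recovery_test()` reports whether and when the median substituted index
reaches a threshold (default 1, the value all indices are normalised to
in year 1).

## The synthetic-data generator

`simulate_region()` emulates exactly the three sufficient data streams
the model consumes, from known yearly parameters drawn around preset
means (logit scale for probabilities, log scale for positive rates):

* counts: the latent trajectory with log-normal noise, rounded to the
  reporting precision of an index, with configurable masked years;
* nests: day-by-day Bernoulli fates through `ep` then `yp` days — so
  failure *timing*, and hence exposure days, is realistic and the
  exposure likelihood is exercised non-trivially — with zero-truncated
  Poisson broods for hatched nests;
* capture histories: Bernoulli survival along the true yearly survival
  path and Bernoulli recapture at the constant per-occasion rate.

The `"northwest-like"`/`"southeast-like"` presets centre the rates on the
published posterior means for the two regions (adult survival 0.46/0.43,
brood 5.78/5.83, egg-stage period survival 0.71/0.71, chick-stage
0.76/0.68, recruitment scaling 0.39/0.41) over 19 years with 150 nests
and 200 new releases per year. Between-year spreads are not published;
the defaults (logit-scale s.d. 0.30 for adult survival, 0.8 for daily
nest survival, log-scale 0.035 for brood and 0.25 for $\rho$) were
chosen once to make the *ranges* of yearly rates comparable to the
published credible intervals of annual variation, and are flagged as
illustrative. Two further values are stated nowhere and were fixed at
field-typical levels: observation s.d. 0.1 (a ~10% sampling CV is the
conventional scale for a regional index) and recapture probability 0.25
(typical of constant-effort passerine ringing).

The `"northwest-recovery"`/`"southeast-recovery"` presets are a stylised
decline-and-recovery contrast for the substitution experiment: both
regions share a survival path with a mid-series dip (0.46, then 0.36 for
four transitions, then 0.48 — survival varies in concert across regions,
as observed), while chick-stage period survival differs (0.82 vs 0.63).
The levels were chosen from the closed-form growth identity so that the
declining region's baseline index stays below 1 after the dip while
donating the other region's productivity recovers it above 1 with a
margin of a couple of years — the qualitative pattern of the motivating
counterfactual — *before* any model was fitted to them.

What the generator does **not** emulate: site-level survey structure and
detectability (counts are already-aggregated indices), within-season
ringing visits, re-nesting after early failure (absorbed by $\rho$, as
in the model itself), dispersal between regions, and density dependence.
Passing tests therefore demonstrate correctness of the estimator and
analyses under the model's own assumptions — not robustness to the many
ways real monitoring data violate them.

## Problem sizes and numerical choices

The test suite runs the full estimator at the study's scale: 20
replicate 19-year scenarios fitted at the default 4 × 20,000
configuration (roughly 45 s per fit), checking that every fit converges,
that ≥90% of the generating yearly survival and productivity values fall
inside their 95% credible intervals, and that the masked year's latent
population is recovered within three posterior s.d. Unit tests use
deliberately small scenarios (6–10 years, tens of nests) so the whole
non-acceptance suite runs in seconds.

Numerical details worth knowing:

* the zero-truncated-Poisson brood term enters JAGS through the "zeros
  trick" with a constant offset, since JAGS has no built-in truncated
  Poisson density;
* the nest-survival terms enter as binomial kernels in (total exposure
  days, failures) — exactly the Mayfield likelihood's sufficient
  statistics;
* `gelman_rubin()` reports `NA` for constant parameters (the anchored
  $N_1$) and excludes them from the convergence flag;
* extinction in the generator is flagged, not raised: the step model's
  zero is absorbing, and downstream code treats all-`NA` count years as
  the validation error they are.

## Limitations

The model inherits the identifiability limits of its data: $\rho_t$ is a
catch-all whose interpretation leans on the other streams being
well-measured; the recapture probability is assumed time-constant; the
index scale (and hence $N_1$) is arbitrary, so only relative trajectories
are meaningful; and the substitution experiments assume no demographic
compensation. Posterior agreement between this implementation and any
other sampler is defined on synthetic data — the original study's
posterior values cannot be reproduced without its proprietary datasets,
and nothing in this package claims to do so.
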