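---
title: "A multistate capture-recapture model for songbird departure and routing decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multistate capture-recapture model for songbird departure and routing decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrateHMM)
```

## The scientific problem

Songbirds staging at a coastal stopover site face two linked decisions
each night: whether to depart (resume migration) and, once airborne,
whether to cross the open sea ("offshore") or to detour along the coast
("onshore"). Automated radio-telemetry networks observe these decisions
imperfectly: coastal flights pass many receiver stations while sea
crossings pass very few, so raw detections over-represent onshore routes.
Ignoring that observation process biases any inference about routing.

`migrateHMM` implements the full chain from raw receiver detections to
detection-corrected posterior summaries:

1. rule-based preprocessing of detections into flights, route labels,
   departure events and encounter histories;
2. a four-state Bayesian multistate capture-recapture model — a hidden
   Markov model — with covariate-linked departure and routing
   probabilities and route- and tag-specific detection probabilities;
3. posterior summaries: species means, migration-distance contrasts, 90%
   highest posterior density intervals (HPDIs), and the latent offshore
   flight count;
4. two auxiliary Bayesian regressions: minimum stopover duration
   (negative binomial) and within-night departure time (Student-t);
5. a synthetic-data generator emulating the whole study design, so every
   stage is testable offline.

## The model

Latent states are `stopover`, `offshore flight`, `onshore flight`,
`departed`; observation codes are the first three plus `not seen`. Every
bird starts in `stopover` ($z_{i,1} = 1$). Per occasion (night) the
transition and observation matrices are

$$
\Omega =
\begin{pmatrix}
1-\psi & \psi\chi & \psi(1-\chi) & 0\\
0 & 0 & 0 & 1\\
0 & 0 & 0 & 1\\
0 & 0 & 0 & 1
\end{pmatrix},
\qquad
\Theta =
\begin{pmatrix}
1 & 0 & 0 & 0\\
0 & p_X & 0 & 1-p_X\\
0 & 0 & p_C & 1-p_C\\
0 & 0 & 0 & 1
\end{pmatrix},
$$

where $\psi$ is the day-to-day departure probability, $\chi$ the
probability that a departure is an offshore flight, and $p_X$, $p_C$ the
detection probabilities for offshore and onshore flights. A flight state
lasts one occasion and is absorbed in `departed`. States and observations
follow categorical distributions row-indexed by the current state.

The departure probability is linked to sunset weather through

$$
\mathrm{logit}(\psi_{i,t}) = \beta^{\psi}_{0,s} +
\beta^{\psi}_{1,s}\,ul_{i,t} + \beta^{\psi}_{2,s}\,uq_{i,t} +
\beta^{\psi}_{3,s}\,vl_{i,t} + \beta^{\psi}_{4,s}\,vq_{i,t} +
\beta^{\psi}_{5,s}\,\Delta p_{i,t} + \beta^{\psi}_{6,s}\,h_{i,t} +
\beta^{\psi}_{7}\,r_{i,t},
$$

with $ul, uq$ ($vl, vq$) orthogonal linear/quadratic bases of the
eastward (northward) wind component, $\Delta p$ the standardized 24-h
pressure change, $h$ standardized relative humidity and $r$ a binary rain
indicator whose slope is shared across species (rainy nights are too rare
to support species interactions). The routing probability uses a species
intercept and shared wind slopes only:

$$
\mathrm{logit}(\chi_{i,t}) = \beta^{\chi}_{0,s} +
\beta^{\chi}_{1}\,ul_{i,t} + \beta^{\chi}_{2}\,uq_{i,t} +
\beta^{\chi}_{3}\,vl_{i,t} + \beta^{\chi}_{4}\,vq_{i,t}.
$$

Detection probabilities are constant over time and indexed by tag type:
`ACT` tags transmit with more power than `NTQB` tags, which is encoded as
a hard ordering constraint ($p^{ACT} \ge p^{NTQB}$) rather than as data.

### Likelihood

The latent states are never integrated by data augmentation; instead the
exact marginal likelihood of each encounter history is computed by the
forward algorithm in log space (`forwardLogLik`, with a C++ kernel for
the sampler). Because a valid history is `stopover ... stopover,
[offshore|onshore|not seen], not seen ...`, the recursion can stop at the
departure occasion — every later factor equals one — which is an exact
shortcut, not an approximation. Histories that remain in stopover through
the last occasion are accepted as right-censored with likelihood
$\prod_t (1-\psi_{i,t})$.

### Covariate bases

The orthogonal polynomial bases are fitted once over all modeled
individual-occasions (the likelihood's support, occasions $1..T-1$) and
stored with their projection coefficients so that predictions on new data
reuse the identical basis. `stats::poly` yields unit-norm columns; the
package rescales them to (approximately) unit standard deviation so all
slopes share the per-SD interpretation of the standardized linear
covariates. Occasion-$t$ sunset covariates drive the transition from
occasion $t$ to $t+1$.

### Priors and sampling

Priors are weakly informative: Normal(0, 1.5) on logit-scale intercepts,
Normal(0, 1) on slopes. The higher (ACT) detection probability gets a
Uniform(0,1) prior; the lower one is the higher times an independent
Uniform(0,1) fraction, which encodes the tag-power ordering in every draw
by construction.

Sampling uses an adaptive random-walk Metropolis algorithm over the
marginal posterior, seeded by a Laplace approximation: the posterior mode
is located by quasi-Newton optimisation and the inverse Hessian seeds
both the proposal covariance (scaled by $2.38^2/d$) and overdispersed
chain starts. During warmup a global step size adapts toward a 23.4%
acceptance rate and freezes afterwards; the proposal covariance stays at
the Laplace curvature, which proved more reliable than re-estimating an
empirical covariance from a short, slowly mixing warmup (the
empirical-covariance adaptation is used only when no curvature is
available). One proposal in ten is drawn
from the (inflated) Laplace approximation itself as an independence
kernel with the exact Metropolis-Hastings correction — this lets a chain
that wandered onto a flat likelihood plateau (e.g. a detection
probability drifting toward 1 while the routing intercept compensates)
jump back to the typical set, and it markedly improves split-Rhat and
effective sample sizes for this posterior's geometry. The default run
configuration is four chains of 2000 iterations including 1000 adaptation
steps; rank-normalized split-Rhat and bulk effective sample size are
computed for every parameter, with flags at Rhat > 1.01 or ESS < 1000.
Runs are deterministic given a seed and this backend.

## Posterior summaries

* `hpdi()` returns the shortest contiguous interval containing
  `ceiling(mass * n)` sorted draws (lowest-start tie-break). It is never
  wider than the equal-tailed interval.
* `speciesMeanDeparture()` averages $\psi$ per draw over each species'
  individual-occasions; the overall mean is the *unweighted* mean across
  species (a weighted version is available via `weighted = TRUE`). The
  same applies to `speciesMeanRouting()`. Averaging at species level was
  chosen because headline means are reported alongside per-species
  values; occasion-weighted averaging is a flag, not the default.
* `distanceContrast()` reports the long-minus-short difference of group
  means per draw.
* `attributeUnknownRoutes()` corrects the offshore count for detection:
  an undetected departure at occasion $d$ is offshore with probability
  $\chi(1-p_X) / [\chi(1-p_X) + (1-\chi)(1-p_C)]$, evaluated at that
  individual's departure-night covariates and tag type. Routes are
  resampled per posterior draw (full uncertainty propagation); the
  plug-in expectation is reported alongside. With the study's detection
  regime ($p_C \approx 0.95$, $p_X \approx 0.5$) an unseen flight is
  attributed offshore with probability near 0.9.

## Preprocessing rules

A *candidate movement* is a maximal run of one tag's detections with
consecutive gaps below 7 h; single-record runs are never flights. A
candidate is a flight when it covered at least 35 km or touched at least
three different receivers. The 35 km criterion uses the great-circle
distance between the first and last detection (endpoint displacement);
a summed track-length alternative is available via `distanceMode =
"track"` since the wording "covered a distance" is ambiguous between the
two — endpoint was chosen as the conservative default and both are
tested.

A flight is *offshore* when it started west of 8.08°E and ended north of
54.135°N, or included a detection at an offshore island station
(Helgoland, FINO3); otherwise onshore.

A *departure* is scored on the antenna with the latest detections when
the mean of the last five detections falls strictly below the mean of the
highest signal strength within the final 10 min before signal loss and
its up to four temporal neighbours (two before, two after; fewer if not
available, with the earliest occurrence of the maximum used when tied).

Exclusions: birds with a minimum stopover above 40 whole days (floor of
deployment-to-departure; 40 exactly is retained), morning-of-deployment
departures of the two nocturnal *Sylvia* species, short westward coastal
flights, and all but each bird's first flight. Every exclusion is logged
with its rule, and retained plus excluded counts always equal the input
count.

Encounter histories are night-indexed: occasion 1 is the deployment day
and a departure $k$ whole days after deployment lands on occasion $k+1$.
Sunset and sunrise are input columns written by the fixture generator;
the pipeline deliberately computes no solar geometry.

## The synthetic study

`simulateStudy()` emulates the field design: 7 species (5 short-distance,
2 long-distance migrants) with the study's tagged sample sizes (289
birds), 36 daily occasions, ACT tags on the three thrushes and NTQB tags
elsewhere, and detection probabilities `pX = (0.55, 0.50)`,
`pC = (0.97, 0.95)` for (ACT, NTQB) — the strong onshore/offshore
detection asymmetry of a coastal receiver network. Weather defaults
(wind sd 4 m/s, pressure-change sd 5 hPa, humidity uniform on 40–100%,
rain probability 10/128) are plausible coastal spring values chosen once
to exercise the quadratic wind terms; the source study reports no
covariate moments, so these are stand-ins, not estimates. Generating
coefficients place species departure probabilities between roughly 0.08
(thrushes) and 0.38 (Garden Warbler) and routing probabilities around
one half, with the Northern Wheatear preferring westward winds.

Raw detection records are materialised so the preprocessing rules can be
exercised end to end: daily stopover pings, a plateau-then-decline
departure signature on the departure night, three-receiver flight tracks
(offshore tracks pass the Helgoland station), and — for a `dropoutProb`
fraction of birds (default 105/289, mirroring tag loss, predation and
battery death) — an abrupt constant-strength signal loss that the
departure rule correctly refuses to score. Birds still in stopover at the
end of the grid are treated as undetermined as well, so the modeled set
contains only birds with determined departures, like the study's 184.
The raw-records round trip is exact: preprocessing the simulated
detections reproduces the simulated encounter histories bit for bit.

What the generator does *not* emulate: spatial and temporal covariate
autocorrelation, real atmospheric fields, heterogeneous deployment dates,
receiver outages, or false-positive detections. Passing tests therefore
demonstrate the correctness of the rules, the likelihood and the
inference machinery under the model's own assumptions — not robustness to
real-data violations of them.

## Auxiliary regressions

For birds with known routing, minimum stopover duration (days, a lower
bound on true stopover) is modeled as negative binomial with log-mean
linear in species, route and their interaction and dispersion $\phi$
(variance $\mu + \mu^2/\phi$; the parameterization is stated because
"negative binomial regression" alone does not pin it down). Relative
departure time (fraction of night length, unbounded for diurnal
departures) is modeled as Student-t with estimated scale and degrees of
freedom ($\nu = 1 + $ Gamma(2, 0.1) a priori, keeping tails heavy but
the likelihood proper). Group means are posterior means of fitted
species-by-route cell means averaged over species within each
migration-distance group; the headline quantities are the short-minus-
long stopover contrast and the onshore-minus-offshore departure-time
shift. Species effects are plain indexed effects with weakly informative
priors — the most direct reading of a "multilevel" structure absent
further detail.

## Numerical choices and degenerate inputs

* Forward recursion in log space with log-sum-exp; impossible histories
  (zero-probability codes under degenerate detection) return `-Inf` with
  a warning rather than erroring.
* `standardizeColumn` refuses zero-variance input; the quadratic basis
  requires three distinct values.
* `hpdi` requires at least 20 draws and breaks ties toward the
  lowest-start window.
* Summary rows are flagged (not silently reported) if the posterior mean
  falls outside its own HPDI, which can happen for multimodal draws.
* Detection probabilities are clamped away from exactly 0/1 only when
  converting a `MultistateParams` to the unconstrained sampler scale.
* The simulator reaches boundary regimes ($\psi \to 0$ or 1) through the
  linear predictor (intercepts of ±20), never through hard-coded
  probabilities, so the simulator and likelihood share one code path.

## Problem sizes

The test suite and the acceptance script run the model at the study's
natural scale (184–289 individuals × 36 occasions; four chains). The
simulation-based calibration check uses 200 individuals × 36 occasions
and 20 replicate fits of the full two-species model — chosen as the
smallest design in which all 25 parameters, including the weakly
identified detection block, remain recoverable. Monte-Carlo checks of
simulator frequencies use 10 000 individuals over short grids.

## Known limitations

* The sampler is a random-walk method: effective sample sizes per draw
  are far below a gradient-based sampler's, and long runs are needed for
  tail quantities. The independence kernel mitigates, but does not
  remove, slow mixing along the $\chi$–detection ridge, which is weakly
  identified wherever covariate variation in $\chi$ is modest.
* Detection probabilities near 1 are shrunk slightly toward the interior
  by the uniform prior at moderate sample sizes.
* No individual random effects; species coefficients are fixed effects,
  matching the model structure implemented.
* The pipeline assumes one deployment site and a single shared occasion
  grid; staggered deployments would need per-bird grids.
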