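# migrateHMM

Bayesian multistate capture–recapture modelling of songbird departure and
routing decisions from automated radio-telemetry.

## The problem

Migratory songbirds staging at a coastal stopover site make two linked
decisions each night: whether to **depart** (resume migration) and, once
airborne, whether to cross the open sea (**offshore**) or detour along the
coast (**onshore**). Automated receiver networks observe these decisions
imperfectly and asymmetrically — a coastal flight passes many stations
while a sea crossing passes almost none — so raw detections are spatially
biased toward onshore routes. Anyone analysing such data (movement
ecologists working with Motus-style telemetry arrays) needs to model the
observation process explicitly before drawing conclusions about routing.

`migrateHMM` implements the full analysis chain:

* **Preprocessing** — rule-based segmentation of raw detections into
  flights (≥ 35 km or ≥ 3 receivers with consecutive detections < 7 h
  apart), route classification (start west of 8.08°E and end north of
  54.135°N, or an offshore island station), departure scoring from the
  signal-strength signature (last five detections below the terminal
  10-min peak window), exclusion rules with a complete accounting log,
  and encounter-history construction over a 36-occasion nightly grid.
* **The multistate model** — a four-state hidden Markov model with states
  *stopover*, *offshore flight*, *onshore flight*, *departed*:

  ```
          ⎛ 1−ψ  ψχ  ψ(1−χ)  0 ⎞            ⎛ 1   0    0    0   ⎞
      Ω = ⎜  0    0    0     1 ⎟        Θ = ⎜ 0  p_X   0  1−p_X ⎟
          ⎜  0    0    0     1 ⎟            ⎜ 0   0   p_C 1−p_C ⎟
          ⎝  0    0    0     1 ⎠            ⎝ 0   0    0    1   ⎠
  ```

  ψ (day-to-day departure probability) is logit-linked to species-specific
  orthogonal quadratic wind terms, pressure change and humidity plus a
  shared rain slope; χ (offshore probability) has species intercepts with
  shared wind slopes; detection probabilities p_X, p_C are tag-type
  specific with an ACT ≥ NTQB ordering constraint. The likelihood is the
  exact marginal forward recursion (latent states integrated out);
  sampling is adaptive Metropolis seeded by a Laplace approximation with
  an independence-kernel component, with rank-normalized split-Rhat and
  bulk ESS diagnostics.
* **Summaries** — species mean ψ and χ, long- vs short-distance migrant
  contrasts, 90% highest posterior density intervals, and the
  detection-corrected offshore flight count: an unseen departure is
  offshore with probability χ(1−p_X) / [χ(1−p_X) + (1−χ)(1−p_C)].
* **Auxiliary regressions** — negative-binomial minimum stopover duration
  and Student-t relative departure time, each with species × route
  structure.
* **Synthetic data** — a generator that emulates the study design end to
  end (7 species, 289 tagged birds, raw detection records, departure
  signatures, tag dropout), so the whole pipeline runs and is tested
  offline.

## Worked example

```r
library(migrateHMM)

study <- simulateStudy(seed = 42)     # full synthetic tracking study
study$modeled                          # birds with determined departures

post <- samplePosterior(poolSpecies(study$modeled), nChains = 4,
                        nIter = 6000, nWarmup = 1000, seed = 42)
max(posteriorDiagnostics(post)$rhat)   # 1.054 (borderline warning: this
                                       # backend likes long chains)

speciesMeanDeparture(post)[, 1:4]
#>            quantity   mean hpdi_lower hpdi_upper
#> 1          Blackcap 0.1407     0.1113      0.167
#> 2           Dunnock 0.1943     0.1399      0.260
#> 3    Garden Warbler 0.3944     0.3179      0.470
#> 4 Northern Wheatear 0.2282     0.1722      0.285
#> 5          thrushes 0.0972     0.0778      0.118
#> 6           overall 0.2110     0.1885      0.236

att <- attributeUnknownRoutes(post, seed = 42)
att$observed
#> offshore  onshore  unknown  modeled
#>       36       89       49      174
att$summary[c(1, 3), 1:4]
#>              quantity   mean hpdi_lower hpdi_upper
#> 1      offshore_count 76.273     69.000     82.000
#> 3 offshore_proportion  0.438      0.397      0.471
```

Reading the output: only 36 of 125 detected flights were offshore (29%),
but after correcting for the detection asymmetry (onshore flights are
seen ~95% of the time, offshore ~50%) the model attributes most of the 49
route-unknown departures to the sea crossing, estimating that 76 birds —
about 44% (90% HPDI 40–47%) of the modeled 174 — flew offshore, close to
the generator's true routing probability of about one half. Per-species
mean departure probabilities span ~0.10 (thrushes) to ~0.39 (Garden
Warbler), matching the generating coefficients.

The staged pipeline (simulate → preprocess → fit → summarize → ppc) is
driven by one configuration:

```r
runPipeline("all", defaultPipelineConfig(),
            overrides = list(paths = list(outDir = "run1")))
```

or from a shell via `inst/scripts/migration-pipeline.R`. Every stage
writes CSV artifacts plus a run log with seeds and filter accounting.

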