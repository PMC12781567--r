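---
title: "Counting wing flaps and modeling their response to wind and swell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting wing flaps and modeling their response to wind and swell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albaflap)
```

## The problem

Albatrosses cover enormous distances during breeding-season foraging trips
while flapping remarkably little, by extracting energy from wind shear
(dynamic soaring) and from updrafts on the windward slopes of traveling
swells (wave-slope soaring). The hourly wing-flap rate, countable from a
bird-borne accelerometer, is a proxy for flight cost, and its dependence on
windspeed and significant swell height quantifies how much work the
environment is doing for the bird. `albaflap` implements the full chain from
raw sensor streams to that dependence:

1. **Flap counting** from the heave (dorsoventral, z) accelerometer axis:
   animal-frame rotation, LULU nonlinear filtering, thresholded peak
   detection, hourly summation.
2. **Behavioural segmentation** of 10-min GPS tracks into resting-on-water,
   foraging and commuting states with a 3-state hidden Markov model (HMM),
   validated against leg-mounted wet/dry immersion loggers; the two flying
   states are grouped as "flight" downstream.
3. **Track-environment synchronization**: hourly positions, wind u/v
   converted to speed (km/h) and meteorological direction, bird-wind and
   bird-swell angles folded onto [0°, 180°], and an hourly modeling table
   restricted to hours of continuous flight.
4. **Flap-rate models**: six generalized additive count models compared by
   small-sample-corrected AIC, a 99% kernel-density trim of the prediction
   space, the percent reduction in flapping from the calm corner to the
   energetic corner of the wind-by-swell space, and a down-sampling
   robustness check.
5. **Context summaries**: foraging-area utilization distributions, monthly
   wind/swell climatologies inside them, tercile condition categories and
   per-species time-in-category proportions.

A seeded synthetic-data generator produces all four input streams with known
ground truth, so every stage is testable without any field data.

## Flap counting

Wingbeats appear as impulsive spikes on the heave axis. The detector works
on the *residual* of the heave signal against a LULU-smoothed baseline.

**Animal-frame rotation.** Tag placement on the back feathers is never
perfectly aligned. A single rigid rotation is estimated from quiescent
segments — the lowest-variance decile of 10 s windows — such that the
low-pass mean acceleration vector maps onto (0, 0, 1 g). If no quiescent
segment exists the global low-pass mean is used with a warning.

**LULU operators.** `L_n` (max of running min) removes upward impulses up to
width `n`; `U_n` (min of running max) removes downward ones. Both are
rank-based, idempotent, and preserve edges — unlike linear filters they do
not smear a spike into its neighbourhood. Finite sequences are evaluated as
on their constant extension (end values replicated), which keeps monotone
sequences exact fixed points at the boundaries; with truncated windows this
property provably fails at the ends.

**Window choice.** The smoother must *remove* each wingbeat spike (so it
survives in the residual) while *not* filling the valleys between
consecutive beats of a bout. That bounds the window between the spike width
and the inter-beat valley width. At 25 Hz with ~3 Hz wingbeats the beat
period is ~8.3 samples; spikes are ~2–4 samples wide and valleys ~5–6, so
the default window is `n = 4` (0.16 s). The default composition `L(U(x))`
has a residual that is non-positive at noise maxima, keeping false peaks
rare; its dual `U(L(x))` under-smooths noise from below and over-detects.
Both are available because real deployments (tag type, attachment, species)
shift the spike morphology — these are per-deployment tuning parameters, not
constants.

**Peak acceptance.** Residual local maxima above the threshold (default
0.5 g, midway between a 0.15 g noise floor and 1.2 g spikes) are accepted
greedily in descending height subject to a refractory gap (default 0.15 s,
under half a wingbeat period); plateau maxima resolve to their first sample.
Counts are summed per UTC clock hour with the half-open convention
`[h, h+1)`, matching the environment grid's time index. Traces recorded at
75 Hz are decimated 3:1 after a 10 Hz zero-phase anti-alias filter.

## Behavioural segmentation

Step lengths (great-circle, haversine with R = 6371 km) and turn angles
(signed change of initial bearing, wrapped to (−π, π]) are computed on the
10-min track. Emissions are gamma for steps — with exact zeros floored at
1 m, since the gamma has no mass at zero — and von Mises for turns, the
standard movement-HMM pairing. Fitting maximizes the exact forward
log-likelihood (scaled recursion, compiled code) by BFGS from 25 seeded
random starts around moment-based initial values; the initial distribution
is tied to the stationary distribution of the transition matrix, and pooled
birds contribute independent likelihood terms (the chain does not bridge
trips). Direct maximization rather than EM keeps the correctness argument
simple: the same likelihood is checked against exhaustive enumeration over
all 3^T paths on short series, and Viterbi decoding against the argmax path
of that enumeration.

Two numerical guards matter. Location-scale mixtures have unbounded
likelihood spikes (a component collapsing onto single observations), so the
working parameters are bounded: emission standard deviations at or above the
1 m step floor and von Mises concentration at most 10^3. States are
relabeled after fitting so mean step length orders rest < forage < commute;
relabeling leaves the likelihood invariant.

**Immersion validation.** A 10-min interval is "GLS-on-water" when any wet
record of duration ≥ 6 s overlaps it (3-s loggers record states of at least
two samples). The agreement statistic is the fraction of HMM-rest intervals
that are GLS-on-water. With a flip-error rate `p` in the synthetic immersion
stream its expectation is `1 − p`, which the tests exploit at `p = 0.02`.

## Track-environment synchronization

Raw GPS is linearly interpolated to the 10-min grid; gaps over 60 min are
left missing rather than bridged. Hourly positions are the interpolated
position at the top of the hour (the hour's mean position is an alternative
the data do not distinguish; top-of-hour is declared and used). Wind
components convert as speed = 3.6·√(u²+v²) km/h and
direction = (270 − atan2(v, u)·180/π) mod 360, the meteorological
coming-from convention. The bird-wind angle is the folded angle between the
travel bearing (hourly displacement, matching the hourly resolution of the
covariates) and the direction the wind blows toward: 0° is a direct
tailwind, 180° a direct headwind; the bird-swell angle is analogous, with a
flag for gridded products that report swell as a going-toward direction.
Spatial extraction is bilinear at the exact hourly field (no temporal
interpolation; directions interpolate on sine/cosine). Hours containing any
rest-decoded interval are dropped so the modeling table reflects flight
only; incomplete trips are retained but flagged, since only the
conditions-experienced summaries exclude them.

The gridded fields travel as long-format CSV (`time, lat, lon, u10, v10,
swh, swd`) with configurable variable names, the package's plain-text
equivalent of the hourly reanalysis arrays it mirrors.

## Flap-rate models

Per species, six penalized-spline models of hourly flap counts:

| Model | Environmental term |
|-------|--------------------|
| 0 | none (intercept) |
| I | `s(windspeed)` |
| II | `s(swell_height)` |
| III | `te(windspeed, BWA)` |
| IV | `te(swell_height, BSA)` |
| V | `te(windspeed, swell_height)` |

every one with a random-intercept smooth for bird identity. The family is
negative binomial with a log link by default (hourly flap counts are
overdispersed; bouts arrive in bursts), Poisson optional. Marginal smooths
use basis dimension 5 and tensor products 5×5. Smoothness is selected by ML,
not REML, because the models are compared by AICc and that comparison needs
a common likelihood definition. The effective degrees of freedom for AICc
(−2ℓ + 2·edf + 2·edf·(edf+1)/(n−edf−1)) are the trace of the influence
matrix plus one for the estimated dispersion; Akaike weights are
exp(−Δ/2) normalized over the candidate set. Folded angles enter the tensor
products as plain bounded covariates — the 0–180° fold removes the
circularity, so no circular basis is used.

**Prediction-space trimming.** Predictions are only interpreted where the
species actually flies: a Gaussian-product KDE with normal-reference
bandwidths over the observed (windspeed, swell height) points, keeping the
region where the density is at least the 1st percentile of its values at the
observed points — so at least ~99% of observations (≥ 98% up to ties) fall
inside.

**The reduction statistic.** Over masked grid cells (equal weights,
linear-interpolation quantiles), the maximum is the 95th and the minimum the
5th quantile of predicted flap rates, and the reduction is
100·(max − min)/max, reported to two decimals. Quantiles are taken over grid
cells rather than observed rows because the statistic describes the
simulated variable space, not the sampling distribution of hours. The
statistic is invariant to rescaling all predictions.

**Down-sampling robustness.** Model V is refitted on replicates of 18
individuals drawn without replacement at a fixed 12:6 brood-guard to
incubation ratio, and per-cell quantile envelopes of the masked surfaces
summarize the variability attributable to sample size.

## Context summaries

Foraging-area utilization uses a Lambert azimuthal equal-area projection
about the colony (distance-true near the colony, no lat/lon distortion at
high latitude), an href-style reference bandwidth
(√((var x + var y)/2)·n^(−1/6)), and the smallest set of grid cells holding
95% of KDE mass. Tercile thresholds of windspeed and swell height come from
a balanced subset — 34 individuals with complete trips per ocean basin,
split as evenly as possible across the species within each basin — as the
1/3 and 2/3 quantiles of the pooled distributions. Relative-angle categories
default to equal 60° bins (tail/with [0°, 60°), cross/across [60°, 120°),
head/against [120°, 180°]); the boundaries are exposed as configuration
because no canonical values exist. Proportions are computed per bird, then
averaged across birds, so unequal trip lengths do not weight the species
summary.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
ground truth exposed:

- **Tracks**: a 3-state Markov chain at 10-min resolution with gamma step
  lengths (defaults 0.1 / 3 / 8 km per 10 min) and von Mises turns; the
  heading in the final 20% of the trip is reflected toward the colony so
  trips are "complete".
- **Acceleration**: 1 g baseline, Gaussian noise (0.15 g), a low-amplitude
  0.1–0.3 Hz soaring undulation (so the filter stage has realistic non-flap
  structure to reject), and flapping bouts in flight states. Bouts are
  placed as a *non-overlapping* renewal process — exponential gaps with the
  rate inflated by 1/(1 − duty cycle) so the expected hourly flap count
  equals the target; overlapping bouts would superimpose spikes and place
  true flaps closer than any refractory gap, an artifact no real bird
  produces. Each bout is a burst of raised-cosine spikes (quarter-period
  half-width) at the wingbeat frequency (default 3 Hz, 1.2 g).
- **Environment**: hourly fields built from spatially smoothed white noise
  evolving as AR(1) across hours; swell is drawn independently of wind,
  mirroring swell generated by distant weather systems.
- **Linkage**: the expected hourly flap rate is
  exp(b₀ + b₁·windspeed + b₂·swell), defaults (log 1500, −0.04 per km/h,
  −0.25 per m) — a calm-corner rate of ~1500 flaps/hour declining to
  ~10% of that in strong wind and high swell, the magnitude regime the
  published per-species reductions (89–93%) describe.
- **Immersion**: rest intervals wet at 3-s resolution, with a 2% default
  flip-error rate; within-bout flap-rate variability is exposed as
  configuration (`flaps_per_bout`) rather than asserted.

Hourly-table simulations for model-recovery studies use a direct generator
(`gen_hourly_table()`): negative binomial counts straight from the true
response with a per-bird random intercept, skipping per-sample synthesis.

**What passing tests do and do not show.** The generator produces clean
wingbeat spikes of a single morphology, stationary noise, and covariates
drawn from smooth fields; real tags add transients, species differ in spike
shape and wingbeat frequency, and real flap-environment coupling is not
exactly log-linear. Recovery results on synthetic data therefore validate
the *correctness* of the implementation, not field-data performance; the
detector threshold and window remain per-deployment tuning parameters.

## Problem sizes and runtimes

The test-suite simulations use sizes chosen to exercise each statistical
claim at meaningful power while staying desk-scale: 100 synthetic hours for
detector recovery (mean relative error < 2%), 2000 intervals for HMM
parameter recovery, 50 seeded cohorts of 600 hours for the model-selection
rate, 5000 fixes for KDE area checks. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch under a
caller-supplied seed.

## Known limitations

- The HMM has no covariate-dependent transition probabilities and the state
  number is fixed at three.
- The detector counts flaps only; it does not separate gait types or
  compute dynamic-body-acceleration metrics.
- Wind-wave (locally generated) sea state is deliberately excluded from the
  models: it is strongly correlated with windspeed and would confound the
  wind/wave comparison; only total swell enters.
- The published per-species AICc tables and condition thresholds depend on
  the field data; the package reproduces the *operations* that produce
  them, and `read_hourly_table()` ingests a deposited hourly summary table
  directly into the modeling stage.
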