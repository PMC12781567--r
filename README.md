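# albaflap

Analysis pipeline for studying how wind and waves shape the flight costs of
albatrosses (and other soaring seabirds) from biologging data. Albatrosses
avoid energetically expensive flapping by dynamic soaring on wind shear and
wave-slope soaring on swell-generated updrafts; the hourly wing-flap rate,
counted from a bird-borne accelerometer, is a proxy for flight cost, and its
joint response to windspeed and significant swell height measures how much
work the environment does for the bird.

The package is aimed at movement ecologists working with tri-axial
accelerometry, GPS tracks, immersion (wet/dry) loggers and gridded
reanalysis wind/wave fields. It implements:

- **Flap counting** — animal-frame rotation, LULU nonlinear smoothers
  (`L_n(x)_i = max_{j∈[i−n,i]} min_{k∈[j,j+n]} x_k` and its dual), and
  thresholded peak detection on the filter residual with a refractory gap;
  counts summed per UTC clock hour.
- **Behavioural states** — a 3-state hidden Markov model (gamma step
  lengths, von Mises turns) on 10-min tracks fitted by direct forward-
  likelihood maximization, Viterbi decoding, and validation of resting
  calls against immersion logs.
- **Track–environment sync** — hourly positions, wind `speed = 3.6·√(u²+v²)`
  km/h with the meteorological coming-from direction, bird-wind and
  bird-swell angles folded to [0°, 180°] (0° tailwind / with the swell,
  180° headwind / against), bilinear field extraction, and an hourly
  modeling table restricted to hours of continuous flight.
- **Flap-rate models** — six GAMs of hourly flap counts (negative binomial,
  log link; tensor-product smooths; random-intercept smooth per bird)
  compared by AICc = −2ℓ + 2·edf + 2·edf·(edf+1)/(n−edf−1); a 99%
  kernel-density trim of the prediction space; the flap-reduction statistic
  `100·(q95 − q5)/q95` over the masked wind×swell surface; conditional
  profiles; and a down-sampling robustness check (replicates of 18 birds at
  a 12:6 stage ratio).
- **Condition context** — 95% kernel utilization regions of foraging
  tracks, monthly wind/swell climatologies inside them, tercile condition
  categories from balanced cross-basin subsets, and per-species proportions
  of time in each category.
- **A synthetic cohort generator** — every input stream (25 Hz
  acceleration, 10-min GPS, 3-s immersion, hourly gridded fields) with
  known ground truth, so the entire pipeline runs and is tested at desk
  scale.

## Worked example

Simulate an hourly modeling table from a known log-linear flap response
(`E[flaps/h] = exp(b0 + b1·windspeed + b2·swell)`), fit the six-model set,
and compute the reduction statistic:

```r
library(albaflap)
cfg  <- sim_config(seed = 42)    # true response: (log 1500, -0.04, -0.25)
tab  <- gen_hourly_table(cfg, n_birds = 30, hours_per_bird = 40, seed = 42)
fits <- fit_model_set(tab)
model_selection_table(fits)
#>   Model                    Term  AICc dAICc     weight      R2      DE
#> 1     V Windspeed, Swell height 15058   0.0  1.000e+00 0.48454 0.54996
#> 2     I               Windspeed 15351 292.8  2.650e-64 0.34634 0.42709
#> 3   III          Windspeed, BWA 15354 296.2  4.724e-65 0.34731 0.42786
#> 4    II            Swell height 15747 689.2 2.218e-150 0.17829 0.21209
#> 5    IV       Swell height, BSA 15750 692.1 5.243e-151 0.18033 0.21293
#> 6     0                    Null 15918 860.4 1.441e-187 0.08046 0.09506

surf <- prediction_surface(fits[["V"]])
flap_reduction(surf)
#> Flap reduction: 87.07% (max 754.3 -> min 97.53 flaps/hour, 897 cells)
```

The selection table mirrors the expected structure: the model with both
windspeed and swell height (Model V) carries essentially all the Akaike
weight, the wind-only family (I/III) beats the swell-only family (II/IV)
because the generating wind effect is the stronger one here, and the null
model is last. The reduction line says that across the plausible (99%
kernel-density) region of the wind×swell space, predicted flapping falls by
87% from its 95th to its 5th quantile — the same statistic that evaluates
to 89–93% for the five published albatross species.

The full pipeline (detection → HMM → sync → models → context) runs from one
call or from the shell:

```r
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 1, n_birds = 6)))
```

```sh
Rscript inst/exec/albaflap run-all --config my_config.yaml
```

A deposited hourly summary table (bird_id, hour, windspeed, swell_height,
BWA, BSA, flaps) can be ingested directly into the modeling stage with
`read_hourly_table()`.

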