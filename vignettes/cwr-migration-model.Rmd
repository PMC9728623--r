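---
title: "Modelling salmonid migration through cold-water refuges"
author: "cwrmigrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling salmonid migration through cold-water refuges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cwrmigrate` is an hourly individual-based model (IBM) of adult summer
steelhead and fall Chinook Salmon migrating upstream through a 302-rkm
dammed river corridor (Bonneville Dam, rkm 235, to the Snake River
confluence, rkm 537).  The corridor's thermal landscape — the
*thermalscape* — combines a warm, well-mixed mainstem with nine tributary
cold-water refuges (CWRs).  The package simulates the full two-species,
four-thermalscape experiment (current/future climate × refuges
available/unavailable) and computes the outcome analytics that such studies
report: accumulated degree-days above 20/21/22 °C, percent of initial
energy reserves used, acute and energetic mortality, arrival timing, and
the coverage area of the energy-conserving migratory phenotype space.

This vignette is the package's methods account: the model structure, every
consequential parameter, what the synthetic data emulate (and do not), the
numerical conventions, and the choices made where the design was genuinely
open.

## Model structure

Each fish carries a state: body mass, stored energy, river position,
behavioural mode (migrating, in a refuge, in a dam tailrace or fishway,
arrived, dead), a motivation clock, and an append-only hourly exposure
log.  One simulated hour proceeds as:

1. **Exposure.** The fish experiences the temperature of its current
   habitat: the mainstem at its river position (linear interpolation in
   rkm between reservoir nodes), the refuge *plume* while entering or
   leaving a refuge, or the refuge *tributary* while holding.  A rolling
   24-h mean is maintained.
2. **Energetics.** Stored energy decreases by a respiration-only
   Wisconsin-style cost
   `oxycal · α · m^β · e^(ρT) · ACT / 24` (kJ h⁻¹), multiplied by 1.62
   in tailraces and 1.26 in fishways.  There is no feeding: adult migrants
   run on their entry reserves, so energy is strictly decreasing.
3. **Mortality.** If energy density falls strictly below 4 kJ g⁻¹ the fish
   dies (energetic death; a fish at exactly 4 survives).  Once per
   completed 24-h exposure block whose mean exceeds the hazard onset, the
   fish survives a Bernoulli draw with probability
   `S(T) = floor + (1 − floor)/(1 + e^{k(T − T50)})`.
4. **Behaviour.** The probability-based decision table selects among
   *advance*, *hold*, *enter refuge*, *exit refuge*:
   - refuge entry probability is zero below a stress onset (19 °C rolling
     mean), rises logistically above it, scales with the fish's
     thermoregulation propensity, decays exponentially with distance to
     the candidate refuge, and is discounted by motivation;
   - the candidate refuge is the coldest currently-qualifying tributary at
     or upstream of the fish within a 10-rkm detection window, subject to
     a density cap (volume × maximum fish density);
   - a migrating fish that does not enter a refuge advances with
     probability `min(1, 0.6 × motivation)` and otherwise station-holds in
     the mainstem at reduced activity — far from their target arrival
     date, fish dawdle; as the target nears they approach full speed;
   - a holding fish leaves when its sampled lognormal residence expires or
     when motivation reaches the exit cutoff.
5. **Dams.** Crossing a dam samples a tailrace behaviour class (day/night
   arrival × fast/slow/very-slow, lognormal durations) and a fishway
   duration whose mean has been calibrated so the Monte-Carlo median of
   total passage time is 19 h ± 15 % per dam.

The *hold* action is what couples refuges to energetics: an hour of
station-holding in a 22 °C mainstem costs several times an hour of holding
in a 10 °C tributary, so refuges act as cheap waiting rooms for fish whose
spawn timing does not yet demand progress.  This is the mechanism by which
refuge availability widens the set of migration strategies that conserve
energy, even though refuge use barely changes the population mean of
energy used: time saved dawdling in warm water is spent holding longer and
arriving later.

## Synthetic study conditions

No external data are used.  The generator reproduces the statistical
structure the analysis needs:

- **Mainstem.** A seasonal sinusoid (peak 23.0 °C on day 230, seasonal
  amplitude 11.8 °C) plus a small diurnal sinusoid (0.3 °C range, warmest
  mid-afternoon) plus clamped AR(1) noise (sd 0.25 °C, hour-to-hour
  correlation 0.995, innovations clamped at 1.8 sd).  July–November daily
  means stay within 15–24 °C and span at least 16–23 °C, the summer
  maximum daily mean lands near 23 °C, and mean diurnal range stays below
  0.5 °C — the low-diurnal-variability regime of a large impounded river
  in a warm year.  All four reservoirs share one curve by default
  (`reach_cooling_gradient = 0`); the reservoirs are treated as well
  mixed.
- **Refuges.** Nine refuges with the surveyed names, volumes (2,988 to
  1,101,126 m³) and July–November temperature targets.  Each tributary
  series is a seasonal sinusoid sharing the mainstem's peak day whose
  amplitude is solved from the published mean and range, so the
  July–November mean matches the published mean to within 0.5 °C and the
  series stays inside the published range; plumes mix tributary and
  mainstem water linearly (default fraction 0.7 toward the tributary).
  Refuge positions, discharges and dam positions (rkm 308, 347, 470) are
  fixture constants, overridable through the map object.
- **Cohorts.** Masses are Normal, truncated above zero (steelhead
  5092 ± 1674 g; Chinook 4279 ± 2088 g); entry dates Normal (Aug 15 ± 15 d;
  Sep 3 ± 6.5 d).  The published "mean ± SE" weights are used as the
  dispersion of the sampling distribution, since a literal standard error
  of the mean is not a usable population spread.  Every fish draws from
  its own seeded sub-stream, so fish *i* is identical whatever the cohort
  size.

What the generator does **not** emulate: flow and velocity fields, thermal
stratification near dams, spatial variability of climate warming,
inter-annual variability, co-occurring non-focal populations, and any
correlation between entry date and body condition.  Tests that pass
against these synthetic conditions demonstrate the mechanics and the
internal consistency of the model, not fidelity to any particular river
year.

## Parameters that matter

| Parameter | Default | Units | Provenance |
|---|---|---|---|
| lethal energy density | 4.0 | kJ g⁻¹ | published threshold |
| tailrace / fishway energy factors | 1.62 / 1.26 | – | published |
| refuge qualification | >0.28 m³ s⁻¹ and ≥2 °C cooler | | published criteria |
| median dam passage target | 19 (±15 %) | h | published calibration target |
| respiration α, β, ρ | 0.00134, 0.783, 0.09 | gO₂ g⁻β d⁻¹, –, °C⁻¹ | literature-scale, calibrated |
| oxycalorific coefficient | 13.56 | kJ (g O₂)⁻¹ | literature |
| initial energy density | 7.5 | kJ g⁻¹ | literature-scale, calibrated |
| activity: migrating / mainstem hold / refuge hold | 4.2 / 1.5 / 1.0 | × standard | calibrated |
| acute survival T₅₀, k, floor, onset | 28.5, 1.6, 0, 20 | °C, °C⁻¹, –, °C | calibrated surrogate |
| stress onset / strong response | 19 / 21 | °C | inside the published 19–22 °C stress range |
| thermoregulation propensity | 0.70 (steelhead), 0.50 (Chinook) | [0,1] | calibrated |
| swim speed | 20 ± 6 / 28 ± 6, floor 8 | km d⁻¹ | inferred, flagged |
| target arrival | Oct 31 ± 10 d / Oct 9 ± 5 d | date | inferred from spawn phenology |
| refuge residence | lognormal, mean 1000, sd 1000 | h | calibrated |
| advance probability base | 0.6 | h⁻¹ | calibrated |
| refuge density cap | 0.1 | fish m⁻³ | non-limiting by design |

"Calibrated" means the value was tuned, once, so that the emergent
population outcomes land in the reported ranges (mean percent energy used
near 28.8 % for steelhead and in the band around 19.6 % for Chinook under
current conditions with refuges; acute mortality in the sub-1 % band under
current and the 1–2 % band under future temperatures; substantial
steelhead refuge use and more modest Chinook use).  The behavioural
decision table's coefficients are model constructs — the table's existence
and inputs are documented in the source study, its cells are not — and all
of them are exposed in `behavior_params()`.

The acute survival curve is an explicit surrogate for unpublished
laboratory values; `t50` and `steepness` are the knobs a survival
uncertainty analysis should vary.  A midpoint near 24 °C — a superficially
natural choice — produces per-block death probabilities around 0.1 at the
synthetic summer peak and population mortality two orders of magnitude
above the reported range, so the default midpoint sits at 28.5 °C where
the logistic tail reproduces the reported 0.2–0.5 % (current) and ≤1.9 %
(future) bands.

## Numerical conventions

- **Degree-days** default to the literal convention: the sum of the hourly
  temperatures themselves (not the excess) over hours above the threshold,
  divided by 24.  The conventional exceedance sum is available via
  `convention = "exceedance"`.
- **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7) everywhere: summary tables, the
  25th-percentile energy-conserving threshold, arrival spreads.
- **Energy-conserving classification** is strict: a fish conserves when
  its percent energy used is strictly below the threshold computed from
  the *current + CWR* run of its species; the same absolute threshold is
  then applied to every other scenario of that species.
- **Phenotype-space areas** are highest-density regions of a Gaussian
  product-kernel density (Scott bandwidth, per cloud) evaluated on a fixed
  256 × 256 grid over the data range padded by 10 %; the HDR at level L is
  the smallest set of grid cells holding L % of the (grid-normalised)
  mass, and its area is cell count × cell area in original units (h²).
  A degenerate cloud returns one grid cell's area as a lower bound.  With
  a few hundred points these areas carry sampling noise of several
  percent; contrasts between scenarios should be read at that resolution.
- **Boundaries.** Energy-density death is strict (`< 4`); residence and
  passage times are floored at one hourly step; the refuge detour is one
  step each way (plume exposure); entry hours are clamped into the
  simulation window; fish remaining at the window end are flagged
  `unabsorbed`, never dropped.
- **Reproducibility.** One master seed drives everything.  Temperature
  fields, the passage calibration, and each fish's behavioural stream use
  independently derived sub-seeds; all within-run randomness is pre-drawn,
  so runs are bitwise reproducible and per-fish trajectories are invariant
  to cohort size except through refuge occupancy.

## Open design choices

Several points were genuinely open; the package's positions are:

- **Corridor geometry** is one-dimensional.  The reported dynamics are
  along-corridor; refuge excursions are lateral and cost a fixed one-step
  detour each way.
- **Refuge choice** is the coldest qualifying tributary within the
  detection window, not merely the nearest: fish are assumed to sense and
  prefer the coolest plume in reach, which keeps seasonally warm refuges
  (e.g. the Umatilla in August) out of use until they actually offer
  relief.
- **Future warming** (+1 °C) applies to the whole thermalscape — mainstem,
  plumes, and refuge tributaries — on the view that a basin-scale warming
  estimate warms source waters too.  `warm_tributaries = FALSE` restores
  the mainstem-only variant.
- **In-refuge exposure** is the tributary temperature while holding and
  the plume while entering/exiting.
- **Acute mortality draws** happen once per completed 24-h block, not per
  hour.
- **Day/night boundary** for tailrace classes is 06:00–18:00.
- The corridor is 302 rkm on the stated endpoints (235 → 537); the
  alternative "288-rkm" figure that circulates for this reach is not
  used.

## Problem sizes

The package's standard analysis scale — used by its test suite and the
bundled acceptance script — is 1000 fish per scenario over the
June–December hourly window (5136 steps), with 2000-fish cohorts and
pooled seeds for mortality rates and 10,000 Monte-Carlo events for passage
calibration.  At this scale the standard error of a population mean of
percent energy used is about 0.2 points, adequate for contrasts of one
point and larger; phenotype-space contractions carry seed-to-seed spreads
of several percentage points, and are interpreted against tolerances of
that order.

## Known limitations

No feeding, growth, or gonad energy allocation; no swimming-speed- or
velocity-dependent activity costs; no downstream fallback at dams; no
harvest, predation, or disease; refuge volumes static in time; a single
synthetic year rather than observed thermographs.  The model is a
mechanism demonstrator for behavioural thermoregulation in a thermally
structured corridor, and its outputs should be read as relative contrasts
between thermalscapes, not absolute predictions for any real stock.

## Running the experiment

```{r, eval = FALSE}
library(cwrmigrate)
ex <- run_experiment(experiment_config(n_fish = 1000, seed = 1))
print(ex)
summary(ex)              # Table-2-style per-scenario summary
plot(ex)                 # arrival densities across thermalscapes
write_experiment_results(ex, "results/")
```
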