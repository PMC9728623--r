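# cwrmigrate

An individual-based simulator of adult Pacific salmonid upstream migration
through a dammed river corridor with cold-water thermal refuges.

## The problem

Upstream-migrating summer steelhead (*Oncorhynchus mykiss*) and fall
Chinook Salmon (*O. tshawytscha*) cross the lower Columbia River corridor
(Bonneville Dam, rkm 235, to the Snake River confluence, rkm 537) during
the warmest part of the year, when mainstem temperatures of 19–22 °C and
above impose physiological stress, drain fixed energy reserves, and at the
extreme kill fish outright.  Nine tributary cold-water refuges (CWRs) —
confluences at least 2 °C cooler than the mainstem with enough flow and
volume to hold adult fish — offer behavioural thermoregulation: a fish can
trade migration progress for hours in cold water.  Whether that trade pays
off depends on entry timing, swim speed, spawn-timing pressure, dam
passage, and the seasonal thermograph, which is exactly the kind of
interacting-process question an individual-based model (IBM) answers.

`cwrmigrate` is for movement ecologists and fisheries modellers who want a
self-contained, reproducible desk-scale version of this experiment: every
input (hourly mainstem and refuge temperature series, migrant cohorts, the
river map) is generated synthetically with the statistical structure the
analysis assumes, so the whole study runs from a single seed with no data
downloads.

## The model

Each fish is stepped hourly through a 1-D corridor:

- **Energetics** — respiration-only Wisconsin-style cost
  `oxycal · α · m^β · e^(ρT) · ACT / 24` (kJ/h) with activity multipliers
  by behavioural mode and dam passage factors ×1.62 (tailrace) / ×1.26
  (fishway); death below an energy density of 4 kJ/g.
- **Behaviour** — a probability-based decision table: refuge entry
  probability rises logistically with the rolling 24-h mean exposure above
  a 19 °C stress onset, scales with thermoregulation propensity, decays
  with distance to the coldest refuge in reach, and is discounted by a
  motivation clock tied to the fish's target arrival date; unmotivated
  fish station-hold; residence in a refuge follows a lognormal draw capped
  by motivation.
- **Dams** — three dams with six tailrace behaviour classes (day/night ×
  fast/slow/very-slow) and a fishway time distribution calibrated by
  bisection so the median total passage time is 19 h ± 15 %.
- **Mortality** — an acute temperature–survival logistic evaluated on each
  completed 24-h exposure block, plus energetic death.
- **Outcomes** — degree-days above 20/21/22 °C (literal sum-of-temperature
  convention), percent energy used, arrival timing densities, exceedance
  (1−CDF) curves, and highest-density-region areas of the
  energy-conserving phenotype space (entry timing relative to the
  temperature peak × travel time outside refuges).

See the methods vignette (`vignettes/cwr-migration-model.Rmd`) for the
full model account, parameter provenance, and design decisions.

## Worked example

```r
library(cwrmigrate)

run <- run_scenario(scenario_config("steelhead", n_fish = 1000, seed = 1))
print(run)
#> <cwr_run> steelhead | current_cwr | n = 1000
#>   fates:   arrived=982  dead_acute=1  dead_energy=17  unabsorbed=0
#>   % energy used: mean 29.5 (sd 6.6), p25 24.6, p75 33.2
#>   refuge users: 79%; mean refuge time 774 h; refusals 0

exceedance_curve(run$outcomes$dd21)(300)
#> [1] 0.612
energy_conserving_threshold(run$outcomes)
#> [1] 24.65
```

Reading: of 1000 simulated steelhead entering around August 15, 982
reached the Snake River confluence; the population used on average 29.5 %
of its initial energy reserves (quartiles 24.6–33.2 %); 79 % of fish used
a cold-water refuge at least once, holding about a month on average, and
no fish was ever turned away by a full refuge.  61 % of fish accumulated
more than 300 degree-days above 21 °C, and a fish counts as
"energy-conserving" when it used less than 24.65 % of its reserves (the
population's 25th percentile).

The full eight-scenario experiment (2 species × current/future ×
with/without refuges), with shared calibration and cached temperature
fields:

```r
ex <- run_experiment(experiment_config(n_fish = 1000, seed = 1))
summary(ex)      # per-scenario energy and mortality summary
plot(ex)         # arrival-timing densities across thermalscapes
write_experiment_results(ex, "results/")
```

A thin command-line front end is installed at
`inst/scripts/cwr-cli.R` (`experiment`, `run`, and `report` subcommands).

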