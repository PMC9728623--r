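# Shared fixtures.  Reference runs are cached per session so several test
# files can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## Calibrated dam template shared by every run.
ref_dam <- function() cached("dam", calibrate_passage(dam_spec(), seed = 1))

## A spatially and temporally constant thermalscape (for closed-form
## checks) built from a zero-noise, zero-amplitude generator.
flat_params <- function(temp = 15)
  mainstem_params(season_peak_temp = temp, seasonal_amplitude = 0,
                  diurnal_amplitude = 0, noise_sd = 0)

flat_scape <- function(temp = 15)
  build_thermalscape(params = flat_params(temp), seed = 1)

## Deterministic single-fish cohort: fixed mass, entry, speed.
point_cohort <- function(species = "steelhead", speed = 20, entry = 227,
                         propensity = 0)
  cohort_params(species, mass_sd = 0, entry_date_mean = entry,
                entry_date_sd = 1e-9, swim_speed_mean = speed,
                swim_speed_sd = 0,
                thermoregulation_propensity = propensity)

damless_map <- function() {
  map <- default_river_map()
  map$dams <- map$dams[0, , drop = FALSE]
  map
}

## Reference scenario runs at the analysis scale (n = 1000, fixed seeds);
## shared by the acceptance suite and the qualitative-ordering tests.
ref_run <- function(species, climate, cwr) {
  name <- paste(species, climate, cwr, sep = "_")
  cached(name, {
    seed <- if (species == "steelhead") 1L else 2L
    cfg <- scenario_config(species, climate = climate, cwr = cwr,
                           n_fish = 1000, seed = seed)
    run_scenario(cfg, dams = config_dams(cfg, calibrated = ref_dam()))
  })
}

## Small traced run for energy bookkeeping / monotonicity invariants.
ref_trace_run <- function() {
  cached("trace_run", {
    cfg <- scenario_config("steelhead", n_fish = 30, seed = 7)
    run_scenario(cfg, dams = config_dams(cfg, calibrated = ref_dam()),
                 trace = TRUE)
  })
}

## Internal helpers exercised directly by the suite.
seasonal_temp <- cwrmigrate:::seasonal_temp
daily_means <- cwrmigrate:::daily_means
p_enter_refuge <- cwrmigrate:::p_enter_refuge
config_dams <- cwrmigrate:::config_dams
arrival_spread_days <- cwrmigrate:::arrival_spread_days
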