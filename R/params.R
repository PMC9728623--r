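# Parameter constructors.  Every tunable of the simulator lives in one of
# these lists so a whole experiment is reproducible from a single config.

# Simulation clock: hours are absolute calendar hours of a 365-day year,
# hour = day_of_year * 24 + hour_of_day.  The default window is
# June 1 00:00 (doy 152) through December 31 23:00.
.SIM_START_DOY <- 152L
.SIM_END_DOY <- 365L

#' Convert between day-of-year and simulation calendar hours
#'
#' The simulator indexes time as absolute calendar hours of a 365-day year
#' (`hour = doy * 24 + hour_of_day`).  These helpers convert in both
#' directions.
#'
#' @param doy Day of year (1-365), possibly fractional.
#' @param hour Calendar hour as used throughout the package.
#' @return `doy_to_hour()` returns the calendar hour at midnight of `doy`;
#'   `hour_to_doy()` returns the (fractional) day of year.
#' @examples
#' doy_to_hour(152)        # June 1 00:00
#' hour_to_doy(doy_to_hour(227) + 12)
#' @export
doy_to_hour <- function(doy) as.integer(round(doy * 24))

#' @rdname doy_to_hour
#' @export
hour_to_doy <- function(hour) hour / 24

## Run a thunk under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a per-stream 31-bit sub-seed from a master seed and stream index.
## Fish i of a scenario always gets the same stream regardless of n_fish.
sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

#' Mainstem temperature generator parameters
#'
#' Controls the synthetic hourly mainstem temperature series: a seasonal
#' sinusoid peaking at `peak_day`, a small diurnal sinusoid, and clamped
#' AR(1) noise.  Defaults emulate a warm recent year in a large, well-mixed
#' impounded river: July-November daily means stay within 15-24 degree C and
#' span at least 16-23 degree C, the summer maximum daily mean falls near
#' 23 degree C, and diurnal range is below 0.5 degree C.
#'
#' @param season_peak_temp Seasonal maximum of the daily-mean curve (degree C).
#' @param peak_day Day of year of the seasonal maximum.
#' @param seasonal_amplitude Peak-to-trough span of the seasonal sinusoid
#'   (degree C).
#' @param diurnal_amplitude Within-day temperature range (degree C); must be
#'   < 0.5 to respect the low diurnal variability of the system.
#' @param noise_sd Stationary standard deviation of the AR(1) hourly noise
#'   (degree C); innovations are clamped at 1.8 sd so daily means stay inside
#'   the stated bounds.
#' @param noise_ar Hour-to-hour autocorrelation of the noise.
#' @param reach_cooling_gradient Longitudinal offset between reservoirs
#'   (degree C per rkm, applied at reservoir nodes; default 0, reservoirs
#'   share one curve).
#' @param sim_start,sim_end Simulation window as days of year.
#' @return A list of class `mainstem_params`.
#' @export
mainstem_params <- function(season_peak_temp = 23.0,
                            peak_day = 230,
                            seasonal_amplitude = 11.8,
                            diurnal_amplitude = 0.3,
                            noise_sd = 0.25,
                            noise_ar = 0.995,
                            reach_cooling_gradient = 0,
                            sim_start = .SIM_START_DOY,
                            sim_end = .SIM_END_DOY) {
  p <- list(season_peak_temp = season_peak_temp, peak_day = peak_day,
            seasonal_amplitude = seasonal_amplitude,
            diurnal_amplitude = diurnal_amplitude,
            noise_sd = noise_sd, noise_ar = noise_ar,
            reach_cooling_gradient = reach_cooling_gradient,
            sim_start = sim_start, sim_end = sim_end)
  class(p) <- "mainstem_params"
  if (sim_start > 152 || sim_end < 335)
    stop("simulation window must cover at least June through December",
         call. = FALSE)
  p
}

#' Cohort (population entry) parameters
#'
#' Species defaults follow the two modelled stocks: Grande Ronde River summer
#' steelhead enter at 5092 +/- 1674 g around August 15 +/- 15 days; Snake
#' River fall Chinook Salmon at 4279 +/- 2088 g around September 3 +/- 6.5
#' days.  The printed "mean +/- SE" entry weights are used as the dispersion
#' (SD) of the sampling distribution, since a literal standard error is not a
#' usable population spread.  Target arrival dates, swim speeds and
#' thermoregulation propensity are not printed for these stocks and carry
#' calibrated defaults (see the methods vignette).
#'
#' @param species `"steelhead"` or `"chinook"`.
#' @param mass_mean,mass_sd Entry body mass distribution (g), truncated > 0.
#' @param entry_date_mean,entry_date_sd Corridor entry date (day of year).
#' @param target_arrival_mean,target_arrival_sd Target arrival at the
#'   corridor terminus (day of year); drives the motivation clock.
#' @param swim_speed_mean,swim_speed_sd Sustained upstream speed (km/day),
#'   truncated at `swim_speed_min`.
#' @param swim_speed_min Lower truncation for swim speed (km/day).
#' @param thermoregulation_propensity Probability scaling of refuge-seeking
#'   behaviour in `[0, 1]`.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(species = c("steelhead", "chinook"),
                          mass_mean = NULL, mass_sd = NULL,
                          entry_date_mean = NULL, entry_date_sd = NULL,
                          target_arrival_mean = NULL, target_arrival_sd = NULL,
                          swim_speed_mean = NULL, swim_speed_sd = 6,
                          swim_speed_min = 8,
                          thermoregulation_propensity = NULL) {
  species <- match.arg(species)
  def <- switch(species,
    steelhead = list(mass_mean = 5092, mass_sd = 1674,
                     entry_date_mean = 227, entry_date_sd = 15,
                     target_arrival_mean = 304, target_arrival_sd = 10,
                     swim_speed_mean = 20,
                     thermoregulation_propensity = 0.70),
    chinook   = list(mass_mean = 4279, mass_sd = 2088,
                     entry_date_mean = 246, entry_date_sd = 6.5,
                     target_arrival_mean = 282, target_arrival_sd = 5,
                     swim_speed_mean = 28,
                     thermoregulation_propensity = 0.5))
  p <- list(species = species,
            mass_mean = mass_mean %||% def$mass_mean,
            mass_sd = mass_sd %||% def$mass_sd,
            entry_date_mean = entry_date_mean %||% def$entry_date_mean,
            entry_date_sd = entry_date_sd %||% def$entry_date_sd,
            target_arrival_mean = target_arrival_mean %||% def$target_arrival_mean,
            target_arrival_sd = target_arrival_sd %||% def$target_arrival_sd,
            swim_speed_mean = swim_speed_mean %||% def$swim_speed_mean,
            swim_speed_sd = swim_speed_sd,
            swim_speed_min = swim_speed_min,
            thermoregulation_propensity =
              thermoregulation_propensity %||% def$thermoregulation_propensity)
  stopifnot(p$mass_mean > 0, p$entry_date_sd > 0,
            p$thermoregulation_propensity >= 0,
            p$thermoregulation_propensity <= 1)
  class(p) <- "cohort_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bioenergetics parameters
#'
#' Respiration-only Wisconsin-style energetics for fasting adult migrants:
#' hourly cost `oxycal * alpha * mass^beta * exp(rho * T) * activity / 24`
#' (kJ/h), with activity multipliers by behavioural mode and fixed dam
#' passage factors (tailrace 1.62, fishway 1.26).  Mortality is imposed when
#' energy density falls strictly below `lethal_energy_density` (4 kJ/g).
#' Coefficient defaults are literature-scale adult-salmonid values tuned so
#' that population-level percent energy used lands in the reported range
#' (see the methods vignette for provenance of every constant).
#'
#' @param resp_alpha Respiration scale (g O2 g^-beta d^-1).
#' @param mass_exponent Allometric exponent on total body mass.
#' @param temp_coeff Exponential temperature coefficient (per degree C);
#'   0.09 corresponds to Q10 of about 2.5.
#' @param act_migrating,act_holding,act_refuge Activity multipliers while
#'   swimming upstream, while station-holding in the mainstem, and while
#'   holding in a refuge (`act_refuge <= act_holding < act_migrating`).
#' @param oxycal Oxycalorific conversion (kJ per g O2).
#' @param initial_energy_density Somatic energy density at corridor entry
#'   (kJ/g).
#' @param lethal_energy_density Energy density below which death is imposed
#'   (kJ/g).
#' @param tailrace_factor,fishway_factor Hourly energy multipliers during dam
#'   passage.
#' @return A list of class `bioenergetics_params`.
#' @export
bioenergetics_params <- function(resp_alpha = 0.00134,
                                 mass_exponent = 0.783,
                                 temp_coeff = 0.09,
                                 act_migrating = 4.2,
                                 act_holding = 1.5,
                                 act_refuge = 1.0,
                                 oxycal = 13.56,
                                 initial_energy_density = 7.5,
                                 lethal_energy_density = 4.0,
                                 tailrace_factor = 1.62,
                                 fishway_factor = 1.26) {
  p <- list(resp_alpha = resp_alpha, mass_exponent = mass_exponent,
            temp_coeff = temp_coeff, act_migrating = act_migrating,
            act_holding = act_holding, act_refuge = act_refuge,
            oxycal = oxycal,
            initial_energy_density = initial_energy_density,
            lethal_energy_density = lethal_energy_density,
            tailrace_factor = tailrace_factor,
            fishway_factor = fishway_factor)
  stopifnot(p$act_refuge < p$act_migrating,
            p$act_refuge <= p$act_holding, p$act_holding < p$act_migrating,
            p$lethal_energy_density < p$initial_energy_density,
            all(unlist(p) > 0))
  class(p) <- "bioenergetics_params"
  p
}

#' Acute thermal survival parameters
#'
#' Logistic surrogate for the laboratory temperature-survival relationship:
#' `S(T) = floor + (1 - floor) / (1 + exp(k * (T - t50)))`, evaluated on the
#' mean of each completed 24-h exposure block whose mean exceeds
#' `hazard_onset`.  `t50` and `k` are the sensitivity knobs of the survival
#' uncertainty hook; defaults are calibrated so population acute mortality
#' sits in the sub-1% (current) and 1-2% (future) bands.
#'
#' @param t50 Temperature of 50% daily survival above the floor (degree C).
#' @param steepness Logistic steepness k (per degree C).
#' @param floor Lower survival asymptote in `[0, 1]`.
#' @param window_h Exposure averaging window (h).
#' @param hazard_onset Block-mean temperature (degree C) below which no
#'   survival draw is made.
#' @return A list of class `acute_survival_params`.
#' @export
acute_survival_params <- function(t50 = 28.5, steepness = 1.6, floor = 0,
                                  window_h = 24, hazard_onset = 20) {
  p <- list(t50 = t50, steepness = steepness, floor = floor,
            window_h = window_h, hazard_onset = hazard_onset)
  stopifnot(p$floor >= 0, p$floor < 1, p$steepness > 0)
  class(p) <- "acute_survival_params"
  p
}

#' Behavioural decision parameters
#'
#' Coefficients of the probability-based decision table (realised as a
#' logistic in thermal stress, scaled by thermoregulation propensity, refuge
#' distance and motivation), refuge residence distribution, motivation ramp,
#' and refuge density limit.  The paper gives the table's existence and its
#' inputs but not its cells; all values here are calibrated defaults
#' (methods vignette, "Behavioural decision table").
#'
#' @param p_base Baseline hourly entry probability scale.
#' @param p_advance_base Baseline hourly probability of advancing upstream
#'   while migrating; multiplied by the motivation factor (capped at 1), so
#'   unmotivated fish station-hold part of the time and approach full speed
#'   as their target arrival nears.
#' @param k_temp Logistic steepness on rolling 24-h mean exposure (per
#'   degree C).
#' @param stress_onset Rolling-mean temperature (degree C) below which refuge
#'   entry probability is exactly zero.
#' @param stress_strong Rolling-mean temperature (degree C) of half-maximal
#'   thermal response.
#' @param dist_scale_rkm e-folding distance of the refuge attraction (rkm).
#' @param detection_window_rkm A refuge is "available" when at or upstream of
#'   the fish within this distance (rkm).
#' @param residence_mean_h,residence_sd_h Lognormal refuge residence time
#'   (arithmetic mean and SD, hours).
#' @param residence_min_h Residence floor (one time step).
#' @param motivation_ramp_days Days before the target arrival over which
#'   motivation ramps from 1 to `motivation_max`.
#' @param motivation_max Saturation value of the motivation factor.
#' @param refuge_exit_motivation Motivation at which a holding fish leaves
#'   its refuge regardless of remaining residence.
#' @param max_density_fish_m3 Refuge capacity per m3 of cold water.
#' @param day_start,day_end Hours of day delimiting "day" arrivals at a dam
#'   tailrace.
#' @param detour_h Lateral detour time to enter or leave a refuge (h).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(p_base = 0.05,
                            p_advance_base = 0.6,
                            k_temp = 1.0,
                            stress_onset = 19,
                            stress_strong = 21,
                            dist_scale_rkm = 5,
                            detection_window_rkm = 10,
                            residence_mean_h = 1000,
                            residence_sd_h = 1000,
                            residence_min_h = 1,
                            motivation_ramp_days = 21,
                            motivation_max = 5,
                            refuge_exit_motivation = 2.5,
                            max_density_fish_m3 = 0.1,
                            day_start = 6, day_end = 18,
                            detour_h = 1) {
  p <- list(p_base = p_base, p_advance_base = p_advance_base,
            k_temp = k_temp, stress_onset = stress_onset,
            stress_strong = stress_strong, dist_scale_rkm = dist_scale_rkm,
            detection_window_rkm = detection_window_rkm,
            residence_mean_h = residence_mean_h,
            residence_sd_h = residence_sd_h,
            residence_min_h = residence_min_h,
            motivation_ramp_days = motivation_ramp_days,
            motivation_max = motivation_max,
            refuge_exit_motivation = refuge_exit_motivation,
            max_density_fish_m3 = max_density_fish_m3,
            day_start = day_start, day_end = day_end, detour_h = detour_h)
  class(p) <- "behavior_params"
  p
}

#' Refuge qualification criteria
#'
#' A candidate cold-water refuge qualifies when its mean August discharge
#' exceeds `min_discharge` (0.28 m3/s, about 10 cfs) and its tributary is at
#' least `cooler_by` (2 degree C) colder than the adjacent mainstem at some
#' hour of the simulation window.
#'
#' @param min_discharge Minimum mean August discharge (m3/s).
#' @param cooler_by Required temperature margin below the mainstem (degree C).
#' @return A list of class `qualification_criteria`.
#' @export
qualification_criteria <- function(min_discharge = 0.28, cooler_by = 2.0) {
  stopifnot(min_discharge > 0, cooler_by > 0)
  structure(list(min_discharge = min_discharge, cooler_by = cooler_by),
            class = "qualification_criteria")
}
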