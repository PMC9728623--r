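# Respiration-only Wisconsin-style bioenergetics, energy-density mortality
# and the acute thermal survival relationship.

#' Hourly respiration cost
#'
#' `oxycal * alpha * mass^beta * exp(rho * temp) * activity / 24` (kJ/h):
#' an exponential-temperature, allometric-mass respiration model for a
#' fasting adult migrant.  Strictly increasing in both mass and
#' temperature.
#'
#' @param mass Body mass (g), > 0.
#' @param temp Experienced temperature (degree C).
#' @param activity Activity multiplier (dimensionless).
#' @param params [bioenergetics_params()].
#' @return Energy cost rate (kJ/h); vectorised over all arguments.
#' @examples
#' p <- bioenergetics_params()
#' 24 * respiration_kjh(5092, 20, p$act_migrating, p)  # ~400 kJ/day migrating
#' @export
respiration_kjh <- function(mass, temp, activity, params = bioenergetics_params()) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  params$oxycal * params$resp_alpha * mass^params$mass_exponent *
    exp(params$temp_coeff * temp) * activity / 24
}

#' Update a fish's energy over a time step
#'
#' Decrements stored energy by `respiration * dt * habitat_factor` and
#' recomputes energy density.  `habitat_factor` is 1 in open water, the
#' tailrace factor (1.62) or fishway factor (1.26) during dam passage;
#' refuge savings enter through the `activity` argument.
#'
#' @param fish A list or one-row data frame with `mass_g` and `energy_kj`.
#' @param temp Experienced temperature (degree C).
#' @param dt Time step (h), >= 0.
#' @param activity Activity multiplier.
#' @param habitat_factor Dam passage multiplier (1 outside dams).
#' @param params [bioenergetics_params()].
#' @return The fish with updated `energy_kj` and `energy_density_kjg`.
#' @export
update_energy <- function(fish, temp, dt, activity = NULL, habitat_factor = 1,
                          params = bioenergetics_params()) {
  stopifnot(dt >= 0)
  if (is.null(activity)) activity <- params$act_migrating
  dec <- respiration_kjh(fish$mass_g, temp, activity, params) * dt *
    habitat_factor
  fish$energy_kj <- fish$energy_kj - dec
  fish$energy_density_kjg <- fish$energy_kj / fish$mass_g
  fish
}

#' Energy-density mortality rule
#'
#' Death is imposed when energy density falls strictly below the lethal
#' threshold (4 kJ/g); a fish exactly at the threshold survives.
#'
#' @param fish A list with `energy_kj` and `mass_g` (or
#'   `energy_density_kjg`).
#' @param params [bioenergetics_params()].
#' @return `TRUE` if the fish dies of energy exhaustion.
#' @export
energy_mortality <- function(fish, params = bioenergetics_params()) {
  dens <- fish$energy_density_kjg %||% (fish$energy_kj / fish$mass_g)
  dens < params$lethal_energy_density
}

#' Acute thermal survival probability
#'
#' Probability of surviving one completed 24-h exposure block as a logistic
#' function of the block's mean temperature:
#' `floor + (1 - floor) / (1 + exp(k * (T - t50)))`.  Non-increasing in
#' temperature and ~1 at 15 degree C under the defaults.
#'
#' @param mean24h_temp Mean temperature of the 24-h block (degree C).
#' @param params [acute_survival_params()].
#' @return Survival probability in `[floor, 1]`; vectorised.
#' @export
acute_survival_probability <- function(mean24h_temp,
                                       params = acute_survival_params()) {
  params$floor + (1 - params$floor) /
    (1 + exp(params$steepness * (mean24h_temp - params$t50)))
}

#' Apply the acute mortality draw for one completed 24-h block
#'
#' Evaluated once per completed 24-h exposure block.  If the block mean
#' exceeds the hazard onset, the fish survives with
#' [acute_survival_probability()]; a uniform draw `u < 1 - survival` kills
#' it (mode `dead_acute`).
#'
#' @param fish A list with `rolling_24h_temps` (the last 24 logged
#'   temperatures) and `mode`.
#' @param u Uniform(0,1) draw (injectable for testing).
#' @param params [acute_survival_params()].
#' @return The fish, with `mode = "dead_acute"` on death.
#' @export
apply_acute_mortality <- function(fish, u = stats::runif(1),
                                  params = acute_survival_params()) {
  temps <- fish$rolling_24h_temps
  if (length(temps) < params$window_h)
    stop("fish must have at least ", params$window_h, " logged hours",
         call. = FALSE)
  m <- mean(temps[seq_len(params$window_h)])
  if (m > params$hazard_onset &&
      u < 1 - acute_survival_probability(m, params))
    fish$mode <- "dead_acute"
  fish
}
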