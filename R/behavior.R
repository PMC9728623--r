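# Behavioural decision surface: refuge entry/exit probabilities, residence
# times, motivation dynamics, and refuge capacity.

## Hourly refuge-entry probability.  Zero below the stress onset; above it,
## logistic in the rolling 24-h mean exposure, scaled by thermoregulation
## propensity, discounted with distance to the refuge and with motivation.
p_enter_refuge <- function(roll24, propensity, dist_rkm, motivation,
                           params = behavior_params()) {
  p <- params$p_base * propensity *
    stats::plogis(params$k_temp * (roll24 - params$stress_strong)) *
    exp(-dist_rkm / params$dist_scale_rkm) *
    pmin(1, 1 / motivation)
  p[roll24 <= params$stress_onset] <- 0
  pmin(pmax(p, 0), 1)
}

#' Motivation factor of the arrival clock
#'
#' Equals 1 far from the target arrival time, ramps linearly over the last
#' `motivation_ramp_days` before the target, and saturates at
#' `motivation_max` from the target onward.  Motivation discounts the
#' refuge-entry probability (favouring upstream advance) and forces refuge
#' exit once it reaches `refuge_exit_motivation`.
#'
#' @param hour Current calendar hour (vectorised).
#' @param target_hour Fish's target arrival hour.
#' @param params [behavior_params()].
#' @return Dimensionless motivation >= 1, non-decreasing in `hour`.
#' @export
motivation_factor <- function(hour, target_hour, params = behavior_params()) {
  ramp <- params$motivation_ramp_days * 24
  frac <- pmin(pmax((hour - (target_hour - ramp)) / ramp, 0), 1)
  1 + (params$motivation_max - 1) * frac
}

#' Is there room in a refuge?
#'
#' Entry is allowed while current occupancy is strictly below capacity
#' (capacity = refuge volume x maximum fish density).
#'
#' @param state A list with `occupants` and `capacity`.
#' @return `TRUE` iff `occupants < capacity`.
#' @export
refuge_entry_allowed <- function(state) {
  stopifnot(state$occupants >= 0)
  state$occupants < state$capacity
}

refuge_capacity <- function(volume, density) pmax(1, floor(volume * density))

#' Sample a refuge residence time
#'
#' Draws from the configured lognormal residence distribution
#' (arithmetic mean `residence_mean_h`, SD `residence_sd_h`), floored at one
#' time step.  A zero-variance configuration returns the mean exactly.
#'
#' @param params [behavior_params()].
#' @param u Optional uniform draw for deterministic replay.
#' @return Residence time in hours (> 0).
#' @export
sample_refuge_residence <- function(params = behavior_params(), u = NULL) {
  if (is.null(u)) u <- stats::runif(1)
  max(params$residence_min_h,
      qlnorm_ms(u, params$residence_mean_h, params$residence_sd_h))
}

#' Decide one fish's action for the current hour
#'
#' The probability-based decision table: a migrating fish enters an
#' available refuge with probability increasing in its rolling 24-h mean
#' exposure above the stress onset and in its thermoregulation propensity,
#' and decreasing with distance to the refuge and with motivation; otherwise
#' it advances.  A holding fish exits when its sampled residence has expired
#' or motivation has reached the exit cutoff, else it holds.  Degenerate
#' contexts (no refuge in reach, refuge full or not currently cool) fall
#' back to advance.
#'
#' @param fish A list with `mode` (`"migrating"` or `"in_refuge"`),
#'   `propensity`, and for holding fish `residence_left_h`.
#' @param context A list: `rolling_mean_24h`, `refuge_dist_rkm` (NA when no
#'   refuge is in reach), `refuge_open` (capacity and coolness check),
#'   `hour`, `target_hour`.
#' @param u Uniform draw for the refuge-entry decision (injectable).
#' @param u_adv Uniform draw for the advance/hold decision.
#' @param params [behavior_params()].
#' @return A list: `action` (one of `"advance"`, `"enter_refuge"`,
#'   `"exit_refuge"`, `"hold"`), `p_enter`, and for migrating fish
#'   `p_advance`.
#' @export
decide_action <- function(fish, context, u = stats::runif(1),
                          u_adv = stats::runif(1),
                          params = behavior_params()) {
  stopifnot(fish$mode %in% c("migrating", "in_refuge"))
  mot <- motivation_factor(context$hour, context$target_hour, params)
  if (fish$mode == "in_refuge") {
    act <- if (fish$residence_left_h <= 0 ||
               mot >= params$refuge_exit_motivation) "exit_refuge" else "hold"
    return(list(action = act, p_enter = 0))
  }
  p <- 0
  if (!is.null(context$refuge_dist_rkm) && !is.na(context$refuge_dist_rkm) &&
      isTRUE(context$refuge_open) &&
      context$refuge_dist_rkm <= params$detection_window_rkm)
    p <- p_enter_refuge(context$rolling_mean_24h, fish$propensity,
                        context$refuge_dist_rkm, mot, params)
  p_adv <- min(1, params$p_advance_base * mot)
  action <- if (u < p) "enter_refuge" else if (u_adv < p_adv) "advance"
            else "hold"
  list(action = action, p_enter = p, p_advance = p_adv)
}
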