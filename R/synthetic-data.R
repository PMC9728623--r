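# Synthetic input generation: hourly mainstem and refuge temperature series
# and migrant cohorts.  These stand in for the monitoring-station and
# telemetry data the original study used, with the statistical structure the
# downstream analysis assumes.

## Pure seasonal component of the mainstem curve (daily scale, degree C).
seasonal_temp <- function(params, doy) {
  half <- params$seasonal_amplitude / 2
  (params$season_peak_temp - half) +
    half * cos(2 * pi * (doy - params$peak_day) / 365)
}

## Clamped AR(1) noise with stationary sd `sd`, hour-to-hour correlation
## `ar`.  Clamping at 1.8 sd keeps daily means inside the stated bounds.
ar1_noise <- function(n, sd, ar, clamp = 1.8) {
  if (sd <= 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - ar^2)
  e <- stats::rnorm(n, 0, innov_sd)
  x <- stats::filter(e, ar, method = "recursive")
  pmin(pmax(as.numeric(x), -clamp * sd), clamp * sd)
}

series_hours <- function(params) {
  seq.int(doy_to_hour(params$sim_start), params$sim_end * 24 + 23)
}

#' Generate the synthetic hourly mainstem temperature series
#'
#' Builds one hourly temperature series per reservoir over the simulation
#' window: a seasonal sinusoid peaking at `peak_day`, a diurnal sinusoid
#' (range `diurnal_amplitude`, warmest mid-afternoon), clamped AR(1) noise,
#' and a per-reservoir longitudinal offset
#' (`reach_cooling_gradient * (node_rkm - origin_rkm)`).  Deterministic for
#' a fixed seed.
#'
#' @param params A [mainstem_params()] list.
#' @param seed Integer seed.
#' @param map A [default_river_map()]-style map supplying reservoir
#'   boundaries.
#' @return A list of class `cwr_series`: `hours` (calendar hours), `temp`
#'   (matrix, hours x reservoirs), `ids`, `node_rkm` (reservoir midpoints).
#' @examples
#' s <- gen_mainstem_series(mainstem_params(noise_sd = 0, diurnal_amplitude = 0), 1)
#' max(s$temp)  # equals the seasonal peak
#' @export
gen_mainstem_series <- function(params = mainstem_params(), seed = 1,
                                map = default_river_map()) {
  stopifnot(inherits(params, "mainstem_params"))
  hours <- series_hours(params)
  doy <- hours / 24
  hod <- hours %% 24
  bounds <- map$reservoir_boundaries
  nodes <- (bounds[-length(bounds)] + bounds[-1]) / 2
  base <- seasonal_temp(params, doy) +
    (params$diurnal_amplitude / 2) * cos(2 * pi * (hod - 15) / 24)
  noise <- with_seed(seed, ar1_noise(length(hours), params$noise_sd,
                                     params$noise_ar))
  offsets <- -params$reach_cooling_gradient * (nodes - map$origin_rkm)
  temp <- outer(base + noise, rep(1, length(nodes))) +
    matrix(offsets, nrow = length(hours), ncol = length(nodes), byrow = TRUE)
  colnames(temp) <- paste0("reservoir_", seq_along(nodes))
  structure(list(hours = hours, temp = temp, ids = colnames(temp),
                 node_rkm = nodes),
            class = "cwr_series")
}

## Mean / extreme of the seasonal cosine over the July-November target
## window; used to solve each refuge's amplitude from its published mean
## and range.
refuge_cos_stats <- function(peak_day) {
  d <- 182:334
  cc <- cos(2 * pi * (d - peak_day) / 365)
  list(mean = mean(cc), min = min(cc), max = max(cc))
}

#' Generate a synthetic refuge tributary temperature series
#'
#' Produces an hourly tributary series whose July-November mean matches the
#' refuge's published mean temperature (within 0.5 degree C) and whose
#' minimum and maximum stay inside the published range (within 1 degree C).
#' The series is a seasonal sinusoid sharing the mainstem's peak day, with
#' amplitude solved from the target mean and range, plus clamped AR(1)
#' noise; the whole series is finally clamped just inside the target range.
#'
#' @param spec One row of a river map's `refuges` data frame (fields
#'   `t_mean`, `t_lo`, `t_hi`), or a list with those fields.
#' @param mainstem A `cwr_series` from [gen_mainstem_series()]; supplies the
#'   hour grid and peak day alignment.
#' @param seed Integer seed.
#' @param peak_day Seasonal peak day (defaults to the mainstem default).
#' @param noise_sd Noise sd (degree C).
#' @return A list of class `cwr_series` with a single-column `temp` matrix.
#' @export
gen_refuge_series <- function(spec, mainstem, seed = 1, peak_day = 230,
                              noise_sd = 0.2) {
  if (spec$t_lo > spec$t_hi)
    stop("refuge temperature target range is inverted", call. = FALSE)
  st <- refuge_cos_stats(peak_day)
  amp_hi <- (spec$t_hi - spec$t_mean) / (st$max - st$mean)
  amp_lo <- (spec$t_mean - spec$t_lo) / (st$mean - st$min)
  amp <- max(0, min(amp_hi, amp_lo))
  mid <- spec$t_mean - st$mean * amp
  doy <- mainstem$hours / 24
  temp <- mid + amp * cos(2 * pi * (doy - peak_day) / 365) +
    with_seed(seed, ar1_noise(length(mainstem$hours), noise_sd, 0.995))
  temp <- pmin(pmax(temp, spec$t_lo - 0.9), spec$t_hi + 0.9)
  m <- matrix(temp, ncol = 1,
              dimnames = list(NULL, spec$id %||% "refuge"))
  structure(list(hours = mainstem$hours, temp = m, ids = colnames(m),
                 node_rkm = NULL),
            class = "cwr_series")
}

#' Generate a migrant cohort
#'
#' Draws `n` fish: body mass ~ Normal(`mass_mean`, `mass_sd`) truncated
#' above 0; entry and target-arrival dates ~ Normal (days), converted to
#' calendar hours; swim speed ~ Normal truncated at `swim_speed_min`.  A
#' pure function of `(params, n, seed)` -- each fish draws from its own
#' seeded sub-stream, so fish `i` is identical regardless of `n`.
#'
#' @param params A [cohort_params()] list.
#' @param n Number of fish (>= 0).
#' @param seed Integer seed.
#' @return A data frame with one row per fish: `fish_id`, `species`,
#'   `mass_g`, `entry_hour`, `target_arrival_hour`, `swim_speed_kmd`,
#'   `propensity`.
#' @examples
#' head(gen_cohort(cohort_params("steelhead"), 5, 1))
#' @export
gen_cohort <- function(params, n, seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  if (length(n) != 1 || is.na(n) || n < 0)
    stop("n must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  cols <- c("mass_g", "entry_doy", "target_doy", "swim_speed_kmd")
  if (n == 0) {
    draws <- matrix(numeric(0), ncol = 4, dimnames = list(NULL, cols))
  } else {
    draws <- t(vapply(seq_len(n), function(i) {
      with_seed(sub_seed(seed, i), {
        mass <- stats::rnorm(1, params$mass_mean, params$mass_sd)
        while (mass <= 0) mass <- stats::rnorm(1, params$mass_mean, params$mass_sd)
        spd <- stats::rnorm(1, params$swim_speed_mean, params$swim_speed_sd)
        while (spd < params$swim_speed_min)
          spd <- stats::rnorm(1, params$swim_speed_mean, params$swim_speed_sd)
        c(mass,
          stats::rnorm(1, params$entry_date_mean, params$entry_date_sd),
          stats::rnorm(1, params$target_arrival_mean, params$target_arrival_sd),
          spd)
      })
    }, numeric(4)))
    colnames(draws) <- cols
  }
  data.frame(fish_id = seq_len(n),
             species = rep(params$species, n),
             mass_g = draws[, "mass_g"],
             entry_hour = as.integer(round(draws[, "entry_doy"] * 24)),
             target_arrival_hour = as.integer(round(draws[, "target_doy"] * 24)),
             swim_speed_kmd = draws[, "swim_speed_kmd"],
             propensity = rep(params$thermoregulation_propensity, n),
             stringsAsFactors = FALSE)
}

## Daily means of a series column (utility shared by tests and diagnostics).
daily_means <- function(series, col = 1) {
  day <- floor(series$hours / 24)
  as.numeric(tapply(series$temp[, col], day, mean))
}
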