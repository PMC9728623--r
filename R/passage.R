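# Dam passage: six tailrace behaviour classes (day/night arrival x
# fast/slow/very-slow), a fishway time distribution, and the iterative
# calibration that matches the median total passage time to the observed
# 19 h per dam.

#' Construct a dam specification
#'
#' Tailrace behaviour is classed by arrival period (day or night) and
#' passage speed (fast, slow, very slow); each of the six classes has a
#' lognormal duration distribution parameterised by arithmetic mean and SD.
#' The class distribution defaults are calibrated stand-ins that
#' [calibrate_passage()] adjusts (through the fishway mean) to the 19-h
#' median.  Energy multipliers are 1.62 (tailrace) and 1.26 (fishway).
#'
#' @param position Dam position (rkm).
#' @param name Dam name.
#' @param class_probs Named numeric of six probabilities (day_fast,
#'   day_slow, day_very_slow, night_fast, night_slow, night_very_slow)
#'   summing to 1.
#' @param class_means,class_sds Tailrace duration mean/SD per class (h).
#' @param fishway_mean_h,fishway_sd_h Fishway duration distribution (h).
#' @param tailrace_energy_factor,fishway_energy_factor Hourly energy
#'   multipliers (> 1).
#' @return A list of class `dam_spec`.
#' @export
dam_spec <- function(position = 308, name = "dam",
                     class_probs = c(day_fast = 0.30, day_slow = 0.15,
                                     day_very_slow = 0.05,
                                     night_fast = 0.30, night_slow = 0.15,
                                     night_very_slow = 0.05),
                     class_means = c(day_fast = 4, day_slow = 14,
                                     day_very_slow = 30,
                                     night_fast = 8, night_slow = 18,
                                     night_very_slow = 34),
                     class_sds = NULL,
                     fishway_mean_h = 7, fishway_sd_h = 3,
                     tailrace_energy_factor = 1.62,
                     fishway_energy_factor = 1.26) {
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must sum to 1", call. = FALSE)
  stopifnot(tailrace_energy_factor > 1, fishway_energy_factor > 1)
  if (is.null(class_sds)) class_sds <- 0.6 * class_means
  structure(list(position = position, name = name,
                 class_probs = class_probs, class_means = class_means,
                 class_sds = class_sds,
                 fishway_mean_h = fishway_mean_h,
                 fishway_sd_h = fishway_sd_h,
                 fishway_scale = 1,
                 tailrace_energy_factor = tailrace_energy_factor,
                 fishway_energy_factor = fishway_energy_factor),
            class = "dam_spec")
}

## Lognormal (meanlog, sdlog) from arithmetic mean and sd; degenerate sd
## gives a point mass at the mean.
lnorm_pars <- function(mean, sd) {
  if (mean <= 0) stop("lognormal mean must be positive", call. = FALSE)
  if (sd <= 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

qlnorm_ms <- function(u, mean, sd) {
  p <- lnorm_pars(mean, sd)
  if (p["sdlog"] == 0) rep(mean, length(u))
  else stats::qlnorm(u, p["meanlog"], p["sdlog"])
}

is_day_hour <- function(hour, day_start = 6, day_end = 18) {
  hod <- hour %% 24
  hod >= day_start & hod < day_end
}

#' Sample a dam passage event
#'
#' Draws the tailrace behaviour class from the class probabilities
#' conditioned on day/night arrival, then tailrace and fishway durations
#' from their lognormal distributions (fishway mean scaled by the
#' calibration factor).  Durations are floored at one time step.
#'
#' @param dam A [dam_spec()].
#' @param arrival_hour Calendar hour of arrival at the tailrace.
#' @param u Optional numeric(3) of uniforms (class, tailrace, fishway) for
#'   deterministic replay; drawn from the session RNG when `NULL`.
#' @param day_start,day_end Day/night boundary (hours of day).
#' @return A list: `tailrace_h`, `fishway_h`, `total_h`, `class`.
#' @export
sample_dam_passage <- function(dam, arrival_hour, u = NULL,
                               day_start = 6, day_end = 18) {
  if (is.null(u)) u <- stats::runif(3)
  period <- if (is_day_hour(arrival_hour, day_start, day_end)) "day" else "night"
  sel <- grep(paste0("^", period, "_"), names(dam$class_probs))
  probs <- dam$class_probs[sel] / sum(dam$class_probs[sel])
  cls <- names(probs)[findInterval(u[1], cumsum(probs), left.open = TRUE) + 1L]
  tail_h <- max(1, qlnorm_ms(u[2], dam$class_means[[cls]], dam$class_sds[[cls]]))
  fway_h <- max(1, qlnorm_ms(u[3], dam$fishway_mean_h * dam$fishway_scale,
                             dam$fishway_sd_h * dam$fishway_scale))
  list(tailrace_h = tail_h, fishway_h = fway_h,
       total_h = tail_h + fway_h, class = cls)
}

## Monte-Carlo median total passage time for a fishway scale factor, on a
## fixed set of pre-drawn uniforms (arrival hours split across day/night).
.passage_median <- function(dam, scale, U, arrival_hours) {
  d <- dam
  d$fishway_scale <- scale
  tot <- vapply(seq_len(nrow(U)), function(i)
    sample_dam_passage(d, arrival_hours[i], U[i, ])$total_h, numeric(1))
  stats::median(tot)
}

#' Calibrate fishway passage time to a target median
#'
#' Iteratively (bisection on a multiplicative fishway-time factor) adjusts
#' the fishway duration distribution until the Monte-Carlo median of total
#' passage time (tailrace + fishway, arrivals spread over day and night)
#' falls within `tolerance` of `target_median_h`.  Deterministic under
#' `seed`.
#'
#' @param dam A [dam_spec()].
#' @param target_median_h Target median total passage time (h); observed
#'   value 19 h per dam.
#' @param tolerance Relative tolerance (default 0.15, the +/-15% band).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param n Number of Monte-Carlo passage events.
#' @param max_iter Maximum bisection iterations before a calibration error.
#' @return The calibrated `dam_spec`, with `fishway_scale` set and the
#'   achieved median in attribute `achieved_median_h`.
#' @export
calibrate_passage <- function(dam, target_median_h = 19, tolerance = 0.15,
                              seed = 1, n = 10000, max_iter = 100) {
  stopifnot(target_median_h > 0)
  U <- with_seed(seed, matrix(stats::runif(3 * n), ncol = 3))
  arrival_hours <- rep(c(10, 22), length.out = n)  # half day, half night
  f <- function(s) .passage_median(dam, s, U, arrival_hours)
  mid <- dam$fishway_scale
  m <- f(mid)
  if (abs(m - target_median_h) > tolerance * target_median_h) {
    if (m < target_median_h) {
      lo <- mid; hi <- mid * 2
      while (f(hi) < target_median_h && hi < 64 * mid) hi <- hi * 2
    } else {
      hi <- mid; lo <- mid / 2
      while (f(lo) > target_median_h && lo > mid / 64) lo <- lo / 2
    }
    it <- 0
    repeat {
      mid <- (lo + hi) / 2
      m <- f(mid)
      if (abs(m - target_median_h) <= tolerance * target_median_h) break
      if (m < target_median_h) lo <- mid else hi <- mid
      it <- it + 1
      if (it > max_iter)
        stop("passage calibration did not converge in ", max_iter,
             " iterations", call. = FALSE)
    }
  }
  dam$fishway_scale <- mid
  attr(dam, "achieved_median_h") <- m
  dam
}
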