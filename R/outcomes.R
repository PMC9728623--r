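# Outcome analytics: degree-days, energy summaries, exceedance and arrival
# curves, and the phenotypic-space coverage analysis.

#' Cumulative degree-days above a threshold
#'
#' Two conventions are provided.  The default, `"literal"`, sums the hourly
#' temperatures themselves whenever they exceed the threshold and divides
#' by 24 to convert hourly sums to days.  The `"exceedance"` alternative
#' sums only the excess above the threshold.
#'
#' @param exposure Hourly temperature exposure series (degree C), non-empty.
#' @param threshold Threshold temperature (degree C).
#' @param convention `"literal"` or `"exceedance"`.
#' @return Degree-days (>= 0).
#' @examples
#' degree_days(rep(21, 24), 20)                 # 21
#' degree_days(rep(21, 24), 20, "exceedance")   # 1
#' @export
degree_days <- function(exposure, threshold,
                        convention = c("literal", "exceedance")) {
  convention <- match.arg(convention)
  exposure <- exposure[!is.na(exposure)]
  if (!length(exposure)) stop("exposure series is empty", call. = FALSE)
  hot <- exposure > threshold
  if (convention == "literal") sum(exposure[hot]) / 24
  else sum(exposure[hot] - threshold) / 24
}

#' Percent of initial energy used
#'
#' @param initial Initial energy (kJ), > 0.
#' @param final Final energy (kJ), <= `initial`.
#' @return `100 * (initial - final) / initial`.
#' @export
percent_energy_used <- function(initial, final) {
  stopifnot(all(initial > 0))
  if (any(final > initial + 1e-9))
    stop("final energy exceeds initial energy", call. = FALSE)
  100 * (initial - final) / initial
}

#' Reverse cumulative distribution (exceedance curve)
#'
#' Returns the right-continuous `1 - ECDF`: the proportion of individuals
#' whose value strictly exceeds `x`.
#'
#' @param values Numeric vector (n >= 1), e.g. per-fish degree-days.
#' @return A function of class `exceedance_curve`; `knots` attribute holds
#'   the sorted unique values.
#' @examples
#' f <- exceedance_curve(c(1, 2, 3)); f(1.5)  # 2/3
#' @export
exceedance_curve <- function(values) {
  stopifnot(length(values) >= 1)
  v <- sort(values)
  n <- length(v)
  f <- function(x) vapply(x, function(q) sum(v > q) / n, numeric(1))
  class(f) <- c("exceedance_curve", "function")
  attr(f, "knots") <- unique(v)
  f
}

absorbed <- function(table) {
  table[table$fate %in% c("arrived", "dead_acute", "dead_energy"), ,
        drop = FALSE]
}

#' Population summary of an outcome table
#'
#' Mean, SD and percentiles (10/25/75/90, linear interpolation between
#' order statistics) of percent energy used over absorbed fish (arrived or
#' dead), plus acute- and energy-mortality percentages (deaths over all
#' fish) and arrival statistics.
#'
#' @param table An outcome table (`cwr_run$outcomes`), n >= 2.
#' @return A one-row data frame.
#' @export
population_summary <- function(table) {
  if (is.null(table) || nrow(table) < 2)
    stop("outcome table must have at least 2 fish", call. = FALSE)
  ab <- absorbed(table)
  pe <- ab$percent_energy_used
  q <- stats::quantile(pe, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  arr <- table$arrival_hour[table$fate == "arrived"]
  arr_q <- if (length(arr))
    stats::quantile(arr / 24, c(0.05, 0.5, 0.95), names = FALSE)
  else rep(NA_real_, 3)
  data.frame(
    n = nrow(table), n_absorbed = nrow(ab),
    mean_pct_energy = mean(pe), sd_pct_energy = stats::sd(pe),
    p10_pct_energy = q[1], p25_pct_energy = q[2],
    p75_pct_energy = q[3], p90_pct_energy = q[4],
    acute_mortality_pct = 100 * sum(table$fate == "dead_acute") / nrow(table),
    energy_mortality_pct = 100 * sum(table$fate == "dead_energy") / nrow(table),
    n_arrived = length(arr),
    arrival_doy_median = arr_q[2],
    arrival_doy_p5 = arr_q[1], arrival_doy_p95 = arr_q[3],
    mean_hours_in_refuge = mean(table$hours_in_refuge),
    prop_refuge_users = mean(table$n_refuge_entries > 0)
  )
}

#' Energy-conserving classification threshold
#'
#' The percent-energy-used value below which a fish counts as
#' energy-conserving: the 25th percentile of percent energy used in the
#' reference population (current conditions with refuges available).
#' Downstream classification marks fish strictly below the threshold.
#'
#' @param table Outcome table of the reference (current + CWR) scenario.
#' @param percentile Percentile defining the threshold (default 25).
#' @return The threshold (% energy used), linear-interpolation convention.
#' @export
energy_conserving_threshold <- function(table, percentile = 25) {
  ab <- absorbed(table)
  stats::quantile(ab$percent_energy_used, percentile / 100, names = FALSE)
}

#' Phenotypic points of the energy-conserving subpopulation
#'
#' Extracts the 2-D phenotype coordinates -- entry timing relative to the
#' mainstem temperature peak (h) and travel time outside refuges (h) -- of
#' arrived fish whose percent energy used falls strictly below the
#' threshold.
#'
#' @param table An outcome table.
#' @param threshold Classification threshold from
#'   [energy_conserving_threshold()].
#' @return A data frame with columns `entry_offset_from_peak_h` and
#'   `travel_time_outside_refuge_h`.
#' @export
phenotype_points <- function(table, threshold) {
  keep <- table$fate == "arrived" & table$percent_energy_used < threshold
  table[keep, c("entry_offset_from_peak_h", "travel_time_outside_refuge_h"),
        drop = FALSE]
}

#' Highest-density-region area of a phenotype point cloud
#'
#' Estimates a 2-D Gaussian-product kernel density (Scott bandwidth) on a
#' fixed 256 x 256 grid spanning the data range padded by 10%, and returns
#' the area of the smallest region containing `level`% of the probability
#' mass (the `level`% HDR).  Areas are reported in the original axis units
#' (h x h).  A degenerate cloud (zero spread on an axis) returns one grid
#' cell's area as a documented lower bound.
#'
#' @param points Two-column data frame or matrix (n >= 10).
#' @param level Coverage level in percent (e.g. 50, 90, 95).
#' @param grid_n Grid resolution per axis.
#' @param pad Fractional range padding.
#' @return Area (h^2).
#' @export
phenotype_space_area <- function(points, level = 95, grid_n = 256,
                                 pad = 0.1) {
  pts <- as.matrix(points)
  if (nrow(pts) < 10)
    stop("phenotype-space density needs at least 10 points", call. = FALSE)
  x <- pts[, 1]; y <- pts[, 2]
  rx <- range(x); ry <- range(y)
  dx <- diff(rx); dy <- diff(ry)
  if (dx == 0 || dy == 0) {
    cell_x <- if (dx == 0) 1 else dx * (1 + 2 * pad) / (grid_n - 1)
    cell_y <- if (dy == 0) 1 else dy * (1 + 2 * pad) / (grid_n - 1)
    return(cell_x * cell_y)
  }
  n <- length(x)
  h_scott <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  lims <- c(rx[1] - pad * dx, rx[2] + pad * dx,
            ry[1] - pad * dy, ry[2] + pad * dy)
  kd <- MASS::kde2d(x, y, h = 4 * h_scott, n = grid_n, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- as.numeric(kd$z)
  mass <- dens * cell
  mass <- mass / sum(mass)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level / 100)[1]
  k * cell
}

#' Percent contraction between two phenotypic-space areas
#'
#' `100 * (area_ref - area_alt) / area_ref`; positive values mean the
#' alternative scenario's energy-conserving space contracted relative to
#' the reference.
#'
#' @param area_ref Reference area (> 0).
#' @param area_alt Alternative area.
#' @return Percent contraction (negative = expansion).
#' @examples
#' space_contraction(100, 77)  # 23
#' @export
space_contraction <- function(area_ref, area_alt) {
  stopifnot(area_ref > 0)
  100 * (area_ref - area_alt) / area_ref
}

#' Smoothed arrival-timing density
#'
#' Gaussian-kernel density of arrival day-of-year over arrived fish;
#' integrates to 1.
#'
#' @param table An outcome table with at least one arrival.
#' @param bandwidth Kernel bandwidth in days.
#' @return A `stats::density` object over day-of-year.
#' @export
arrival_density <- function(table, bandwidth = 3) {
  arr <- table$arrival_hour[table$fate == "arrived"] / 24
  if (!length(arr)) stop("no arrivals in the outcome table", call. = FALSE)
  stats::density(arr, bw = bandwidth)
}

## Width of the middle-90% arrival interval (days).
arrival_spread_days <- function(table) {
  arr <- table$arrival_hour[table$fate == "arrived"] / 24
  diff(stats::quantile(arr, c(0.05, 0.95), names = FALSE))
}
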