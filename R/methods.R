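# S3 methods for the run and experiment objects.

#' @export
print.cwr_run <- function(x, ...) {
  o <- x$outcomes
  cat("<cwr_run> ", unique(o$species), " | ", x$scenario,
      " | n = ", nrow(o), "\n", sep = "")
  tab <- table(factor(o$fate, levels = c("arrived", "dead_acute",
                                         "dead_energy", "unabsorbed")))
  cat("  fates:  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  if (nrow(o) >= 2) {
    s <- population_summary(o)
    cat(sprintf("  %% energy used: mean %.1f (sd %.1f), p25 %.1f, p75 %.1f\n",
                s$mean_pct_energy, s$sd_pct_energy, s$p25_pct_energy,
                s$p75_pct_energy))
    cat(sprintf("  refuge users: %.0f%%; mean refuge time %.0f h; refusals %d\n",
                100 * s$prop_refuge_users, s$mean_hours_in_refuge,
                x$refusals_total))
  }
  invisible(x)
}

#' Summarise a scenario run
#'
#' @param object A `cwr_run`.
#' @param ... Unused.
#' @return The [population_summary()] row for the run's outcome table.
#' @export
summary.cwr_run <- function(object, ...) population_summary(object$outcomes)

#' Plot a scenario run
#'
#' Two-panel base-graphics display: smoothed arrival-timing density and the
#' degree-day exceedance curve at a chosen threshold.
#'
#' @param x A `cwr_run`.
#' @param threshold Degree-day threshold column to plot (20, 21 or 22).
#' @param ... Passed to `plot`.
#' @export
plot.cwr_run <- function(x, threshold = 21, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  o <- x$outcomes
  if (any(o$fate == "arrived")) {
    d <- arrival_density(o)
    plot(d, main = paste(unique(o$species), x$scenario),
         xlab = "arrival day of year", ...)
  }
  col <- paste0("dd", threshold)
  f <- exceedance_curve(o[[col]])
  xs <- seq(0, max(o[[col]]) * 1.05 + 1e-9, length.out = 200)
  plot(xs, f(xs), type = "s", xlab = paste0("degree-days > ", threshold,
                                            " degree C"),
       ylab = "proportion exceeding", main = "accumulated exposure", ...)
  invisible(x)
}

#' @export
print.cwr_experiment <- function(x, ...) {
  cat("<cwr_experiment> seed", x$manifest$seed, "| n per scenario",
      x$manifest$n_fish, "\n")
  cat(sprintf("calibrated median dam passage: %.1f h (fishway scale %.2f)\n",
              x$manifest$passage_median_h, x$manifest$fishway_scale))
  cols <- c("species", "scenario", "mean_pct_energy", "sd_pct_energy",
            "p25_pct_energy", "p75_pct_energy", "acute_mortality_pct")
  tab <- x$summary[, cols]
  tab[, -(1:2)] <- round(tab[, -(1:2)], 2)
  print(tab, row.names = FALSE)
  for (sp in names(x$phenotype)) {
    ph <- x$phenotype[[sp]]
    cat(sprintf(
      "%s: energy-conserving threshold %.1f%%; 95%% space contraction: no-CWR %+.1f%%, warming %+.1f%%\n",
      sp, ph$threshold_pct, ph$contraction_no_cwr_pct,
      ph$contraction_warming_pct))
  }
  invisible(x)
}

#' Summarise an experiment
#'
#' @param object A `cwr_experiment`.
#' @param ... Unused.
#' @return The per-scenario summary table.
#' @export
summary.cwr_experiment <- function(object, ...) object$summary

#' Plot an experiment
#'
#' Arrival-density comparison across the four thermalscapes, one panel per
#' species.
#'
#' @param x A `cwr_experiment`.
#' @param ... Unused.
#' @export
plot.cwr_experiment <- function(x, ...) {
  sps <- names(x$phenotype)
  op <- graphics::par(mfrow = c(1, length(sps)))
  on.exit(graphics::par(op))
  scen <- c("current_cwr", "current_nocwr", "future_cwr", "future_nocwr")
  cols <- c("blue4", "skyblue3", "red3", "salmon")
  for (sp in sps) {
    first <- TRUE
    for (i in seq_along(scen)) {
      run <- x$runs[[paste0(sp, "_", scen[i])]]
      if (is.null(run) || !any(run$outcomes$fate == "arrived")) next
      d <- arrival_density(run$outcomes)
      if (first) {
        plot(d, col = cols[i], main = sp, xlab = "arrival day of year")
        first <- FALSE
      } else graphics::lines(d, col = cols[i])
    }
    graphics::legend("topright", legend = scen, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
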