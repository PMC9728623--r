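# Full-experiment orchestration: 2 species x {current, future} x
# {CWR, no-CWR} from one config, with shared calibration, cached
# thermalscapes, and a reproducibility manifest.

#' Experiment configuration
#'
#' One config drives the whole eight-scenario experiment.  A single master
#' seed determines calibration, temperature fields, cohorts and behaviour.
#'
#' @param n_fish Fish per scenario.
#' @param seed Master seed.
#' @param species Character vector of species to simulate.
#' @param map,mainstem,bio,acute,behavior,criteria Shared parameter blocks.
#' @param cohorts Named list of [cohort_params()] per species (defaults per
#'   species).
#' @param warming_delta Future warming (degree C).
#' @param warm_tributaries Warm refuge tributaries too?
#' @param mixing_fraction Plume mixing fraction.
#' @param dam_template,passage_target_h,passage_tolerance Dam passage
#'   template and calibration target.
#' @param coverage_levels HDR coverage levels (%) for the phenotype-space
#'   report.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_fish = 1000, seed = 1,
                              species = c("steelhead", "chinook"),
                              map = default_river_map(),
                              mainstem = mainstem_params(),
                              bio = bioenergetics_params(),
                              acute = acute_survival_params(),
                              behavior = behavior_params(),
                              criteria = qualification_criteria(),
                              cohorts = NULL,
                              warming_delta = 1,
                              warm_tributaries = TRUE,
                              mixing_fraction = 0.7,
                              dam_template = dam_spec(),
                              passage_target_h = 19,
                              passage_tolerance = 0.15,
                              coverage_levels = c(50, 90, 95)) {
  if (is.null(cohorts))
    cohorts <- stats::setNames(lapply(species, cohort_params), species)
  cfg <- list(n_fish = as.integer(n_fish), seed = as.integer(seed),
              species = species, map = map, mainstem = mainstem, bio = bio,
              acute = acute, behavior = behavior, criteria = criteria,
              cohorts = cohorts, warming_delta = warming_delta,
              warm_tributaries = warm_tributaries,
              mixing_fraction = mixing_fraction,
              dam_template = dam_template,
              passage_target_h = passage_target_h,
              passage_tolerance = passage_tolerance,
              coverage_levels = coverage_levels)
  class(cfg) <- "experiment_config"
  cfg
}

scenario_from_experiment <- function(cfg, species, climate, cwr) {
  scenario_config(species = species, climate = climate, cwr = cwr,
                  n_fish = cfg$n_fish,
                  seed = cfg$seed + match(species, cfg$species) - 1L,
                  warming_delta = cfg$warming_delta,
                  warm_tributaries = cfg$warm_tributaries,
                  map = cfg$map, mainstem = cfg$mainstem,
                  cohort = cfg$cohorts[[species]], bio = cfg$bio,
                  acute = cfg$acute, behavior = cfg$behavior,
                  criteria = cfg$criteria,
                  mixing_fraction = cfg$mixing_fraction,
                  dam_template = cfg$dam_template,
                  passage_target_h = cfg$passage_target_h,
                  passage_tolerance = cfg$passage_tolerance)
}

#' Validate a configuration
#'
#' Checks the invariants of every nested parameter block and returns a data
#' frame of findings, distinguishing errors (simulation would be invalid)
#' from warnings (values outside the documented envelope).
#'
#' @param config A [scenario_config()] or [experiment_config()].
#' @return Data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg) findings[[length(findings) + 1]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  if (!is.null(config$n_fish) && config$n_fish < 0)
    add("error", "n_fish must be non-negative")
  ms <- config$mainstem
  if (!is.null(ms)) {
    if (ms$diurnal_amplitude >= 0.5)
      add("warning",
          "diurnal amplitude >= 0.5 degree C exceeds the low-diurnal-variability envelope (< 0.5)")
    if (ms$sim_start > 152 || ms$sim_end < 335)
      add("error", "simulation window must cover June-December")
  }
  bio <- config$bio
  if (!is.null(bio)) {
    if (bio$act_refuge >= bio$act_migrating)
      add("error", "refuge activity multiplier must be below the migrating multiplier")
    if (bio$lethal_energy_density >= bio$initial_energy_density)
      add("error", "lethal energy density must be below the initial energy density")
  }
  tryCatch(validate_river_map(config$map),
           error = function(e) add("error", conditionMessage(e)))
  cohorts <- config$cohorts %||% list(config$cohort)
  for (ch in cohorts) {
    if (is.null(ch)) next
    if (ch$mass_mean <= 0) add("error", "cohort mass_mean must be positive")
    if (ch$thermoregulation_propensity < 0 ||
        ch$thermoregulation_propensity > 1)
      add("error", "thermoregulation propensity must lie in [0, 1]")
  }
  if (!length(findings))
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Run the full four-thermalscape experiment
#'
#' Calibrates dam passage once, builds the current thermalscape once per
#' experiment (future/no-CWR variants are derived transforms of the same
#' field), runs all `species x {current, future} x {cwr, nocwr}` scenarios,
#' and assembles the reported analytics: a per-scenario energy/mortality
#' summary table, degree-day exceedance values, arrival densities, and the
#' energy-conserving phenotype-space report (classification thresholds
#' computed from the current + CWR run of each species only, then applied
#' to all of that species' scenarios).
#'
#' @param config An [experiment_config()].
#' @return An object of class `cwr_experiment`: `summary` (one row per
#'   scenario), `runs` (named list of `cwr_run`), `thresholds`,
#'   `phenotype` (areas and contractions per species), `manifest`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  v <- validate_config(config)
  if (any(v$level == "error"))
    stop("invalid experiment config:\n  ",
         paste(v$message[v$level == "error"], collapse = "\n  "),
         call. = FALSE)
  dams_tmpl <- calibrate_passage(config$dam_template,
                                 config$passage_target_h,
                                 config$passage_tolerance,
                                 seed = sub_seed(config$seed, 909))
  grid <- expand.grid(cwr = c(TRUE, FALSE), climate = c("current", "future"),
                      species = config$species, stringsAsFactors = FALSE)
  runs <- list()
  summaries <- list()
  scape_cache <- list()
  for (r in seq_len(nrow(grid))) {
    sp <- grid$species[r]; cl <- grid$climate[r]; cw <- grid$cwr[r]
    scfg <- scenario_from_experiment(config, sp, cl, cw)
    key <- as.character(scfg$seed)
    if (is.null(scape_cache[[key]]))
      scape_cache[[key]] <- build_thermalscape(
        config$map, config$mainstem, seed = scfg$seed,
        criteria = config$criteria,
        mixing_fraction = config$mixing_fraction)
    run <- run_scenario(scfg, scape = scape_cache[[key]],
                        dams = config_dams(scfg, calibrated = dams_tmpl))
    label <- paste(sp, run$scenario, sep = "_")
    runs[[label]] <- run
    s <- population_summary(run$outcomes)
    summaries[[label]] <- cbind(data.frame(species = sp,
                                           scenario = run$scenario,
                                           stringsAsFactors = FALSE), s)
  }
  summary_tab <- do.call(rbind, summaries)
  rownames(summary_tab) <- NULL

  thresholds <- list(); phenotype <- list()
  for (sp in config$species) {
    ref <- runs[[paste0(sp, "_current_cwr")]]$outcomes
    thr <- energy_conserving_threshold(ref)
    thresholds[[sp]] <- thr
    areas <- list()
    for (lbl in grep(paste0("^", sp, "_"), names(runs), value = TRUE)) {
      pts <- phenotype_points(runs[[lbl]]$outcomes, thr)
      areas[[sub(paste0("^", sp, "_"), "", lbl)]] <-
        vapply(config$coverage_levels, function(lv)
          if (nrow(pts) >= 10) phenotype_space_area(pts, lv) else NA_real_,
          numeric(1))
    }
    a95 <- vapply(areas, function(a) a[length(config$coverage_levels)],
                  numeric(1))
    contr <- function(ref, alt)
      if (is.na(ref) || is.na(alt) || ref <= 0) NA_real_
      else space_contraction(ref, alt)
    phenotype[[sp]] <- list(
      threshold_pct = thr,
      areas = areas,
      contraction_no_cwr_pct =
        contr(a95[["current_cwr"]], a95[["current_nocwr"]]),
      contraction_warming_pct =
        contr(a95[["current_cwr"]], a95[["future_cwr"]]))
  }
  field_sig <- vapply(scape_cache, function(s) sum(s$mainstem$temp),
                      numeric(1))
  out <- list(summary = summary_tab, runs = runs, thresholds = thresholds,
              phenotype = phenotype,
              manifest = list(seed = config$seed, n_fish = config$n_fish,
                              fishway_scale = dams_tmpl$fishway_scale,
                              passage_median_h =
                                attr(dams_tmpl, "achieved_median_h"),
                              mainstem_field_signature = field_sig),
              config = config)
  class(out) <- "cwr_experiment"
  out
}
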