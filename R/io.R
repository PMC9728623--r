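# Serialization: temperature series as delimited text, configs as YAML,
# outcome tables as TSV.

#' Write / read an hourly temperature series as delimited text
#'
#' Long format with columns `hour` (calendar hour), `id` (reach or refuge),
#' `temp_C`; tab-separated.  A whole thermalscape round-trips through this
#' format (`write_temperature_series(scape, ...)` writes mainstem and
#' tributary series together).
#'
#' @param x A `cwr_series` or `thermalscape`.
#' @param path Output file path.
#' @return `write_temperature_series()` returns `path` invisibly;
#'   `read_temperature_series()` returns a `cwr_series` (ids become
#'   columns).
#' @export
write_temperature_series <- function(x, path) {
  if (inherits(x, "thermalscape")) {
    long <- rbind(series_long(x$mainstem),
                  series_long(list(hours = x$hours, temp = x$trib,
                                   ids = colnames(x$trib))))
  } else long <- series_long(x)
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

series_long <- function(s) {
  if (!ncol(s$temp))
    return(data.frame(hour = integer(0), id = character(0),
                      temp_C = numeric(0)))
  data.frame(hour = rep(s$hours, times = ncol(s$temp)),
             id = rep(colnames(s$temp), each = length(s$hours)),
             temp_C = as.numeric(s$temp), stringsAsFactors = FALSE)
}

#' @rdname write_temperature_series
#' @export
read_temperature_series <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(long$id)
  hours <- sort(unique(long$hour))
  temp <- matrix(NA_real_, nrow = length(hours), ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (id in ids) {
    sub <- long[long$id == id, ]
    temp[match(sub$hour, hours), id] <- sub$temp_C
  }
  structure(list(hours = hours, temp = temp, ids = ids, node_rkm = NULL),
            class = "cwr_series")
}

#' Write / read an experiment configuration as YAML
#'
#' Serialises every parameter block (including the river map) to a nested
#' human-editable YAML file and restores it, so an experiment is a pure
#' function of its config file.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns the `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$map <- list(origin_rkm = x$map$origin_rkm,
                terminus_rkm = x$map$terminus_rkm,
                dams = as.list(x$map$dams),
                refuges = as.list(x$map$refuges),
                reservoir_boundaries = x$map$reservoir_boundaries)
  x$cohorts <- lapply(x$cohorts, unclass)
  for (blk in c("mainstem", "bio", "acute", "behavior", "criteria",
                "dam_template"))
    x[[blk]] <- unclass(x[[blk]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  map <- structure(list(origin_rkm = x$map$origin_rkm,
                        terminus_rkm = x$map$terminus_rkm,
                        dams = as.data.frame(x$map$dams,
                                             stringsAsFactors = FALSE),
                        refuges = as.data.frame(x$map$refuges,
                                                stringsAsFactors = FALSE),
                        reservoir_boundaries =
                          unlist(x$map$reservoir_boundaries)),
                   class = "river_map")
  restore <- function(lst, cls) structure(lst, class = cls)
  cohorts <- lapply(x$cohorts, restore, cls = "cohort_params")
  experiment_config(
    n_fish = x$n_fish, seed = x$seed, species = unlist(x$species),
    map = map,
    mainstem = do.call(mainstem_params, x$mainstem),
    bio = do.call(bioenergetics_params, x$bio),
    acute = do.call(acute_survival_params,
                    x$acute[c("t50", "steepness", "floor", "window_h",
                              "hazard_onset")]),
    behavior = do.call(behavior_params, x$behavior),
    criteria = do.call(qualification_criteria, x$criteria),
    cohorts = cohorts,
    warming_delta = x$warming_delta,
    warm_tributaries = x$warm_tributaries,
    mixing_fraction = x$mixing_fraction,
    dam_template = restore(x$dam_template, "dam_spec"),
    passage_target_h = x$passage_target_h,
    passage_tolerance = x$passage_tolerance,
    coverage_levels = unlist(x$coverage_levels))
}

#' Write outcome tables and summaries of an experiment to a directory
#'
#' Emits per-scenario outcome tables (`outcomes_<label>.tsv`), the summary
#' table (`summary.tsv`), the phenotype-space report
#' (`phenotype_report.yaml`) and the manifest (`manifest.yaml`).
#'
#' @param experiment A `cwr_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_results <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lbl in names(experiment$runs))
    utils::write.table(experiment$runs[[lbl]]$outcomes,
                       file.path(dir, paste0("outcomes_", lbl, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(experiment$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ph <- lapply(experiment$phenotype, function(p)
    list(threshold_pct = as.numeric(p$threshold_pct),
         areas_h2 = lapply(p$areas, as.numeric),
         contraction_no_cwr_pct = as.numeric(p$contraction_no_cwr_pct),
         contraction_warming_pct = as.numeric(p$contraction_warming_pct)))
  yaml::write_yaml(ph, file.path(dir, "phenotype_report.yaml"))
  yaml::write_yaml(experiment$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
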