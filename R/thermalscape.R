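# Thermalscape assembly: mainstem field + refuge units, refuge
# qualification, plume mixing, future warming and refuge removal.

#' Plume temperature from the linear mixing model
#'
#' A refuge plume mixes tributary and mainstem water:
#' `mixing_fraction * t_trib + (1 - mixing_fraction) * t_main`.  The result
#' is always bounded by its two sources.
#'
#' @param t_trib Tributary temperature (degree C).
#' @param t_main Mainstem temperature (degree C).
#' @param mixing_fraction Fraction of tributary water in the plume, in
#'   `[0, 1]`.
#' @return Plume temperature (degree C); vectorised.
#' @examples
#' plume_temperature(12, 20, 0.5)  # 16
#' @export
plume_temperature <- function(t_trib, t_main, mixing_fraction) {
  if (any(mixing_fraction < 0) || any(mixing_fraction > 1))
    stop("mixing_fraction must lie in [0, 1]", call. = FALSE)
  mixing_fraction * t_trib + (1 - mixing_fraction) * t_main
}

#' Assemble a scenario thermalscape
#'
#' Generates the mainstem field and the nine refuge tributary series for a
#' river map, applies refuge qualification, and packages everything as a
#' `thermalscape`.  Refuge series use sub-seeds derived from `seed`, so the
#' whole field is a pure function of `(map, params, seed)`.
#'
#' @param map A [default_river_map()]-style river map.
#' @param params [mainstem_params()].
#' @param seed Integer seed for the temperature fields.
#' @param criteria [qualification_criteria()] applied to the candidate
#'   refuges.
#' @param mixing_fraction Plume mixing fraction toward the tributary.
#' @return A list of class `thermalscape`: `hours`, `mainstem` (`cwr_series`),
#'   `refuges` (qualified refuge table), `trib` (matrix hours x refuges),
#'   `mixing_fraction`, `scenario` (`climate`, `cwr`), `warming_delta`,
#'   `peak_hour` (calendar hour of the maximum mainstem daily mean), `map`.
#' @export
build_thermalscape <- function(map = default_river_map(),
                               params = mainstem_params(),
                               seed = 1,
                               criteria = qualification_criteria(),
                               mixing_fraction = 0.7) {
  mainstem <- gen_mainstem_series(params, seed, map)
  cand <- map$refuges
  trib <- matrix(0, nrow = length(mainstem$hours), ncol = nrow(cand),
                 dimnames = list(NULL, cand$id))
  for (j in seq_len(nrow(cand)))
    trib[, j] <- gen_refuge_series(cand[j, ], mainstem,
                                   seed = sub_seed(seed, 100 + j),
                                   peak_day = params$peak_day)$temp[, 1]
  scape <- structure(
    list(hours = mainstem$hours, mainstem = mainstem, refuges = cand,
         trib = trib, mixing_fraction = mixing_fraction,
         scenario = list(climate = "current", cwr = TRUE),
         warming_delta = 0,
         peak_hour = peak_hour_of(mainstem),
         uniform_mainstem = params$reach_cooling_gradient == 0,
         map = map, criteria = criteria),
    class = "thermalscape")
  keep <- qualify_refuges(cand, scape, criteria, .ids = TRUE)
  scape$refuges <- cand[cand$id %in% keep, , drop = FALSE]
  scape$trib <- trib[, scape$refuges$id, drop = FALSE]
  scape
}

## Calendar hour of the maximum daily mean of the first reservoir series.
peak_hour_of <- function(mainstem) {
  day <- floor(mainstem$hours / 24)
  dm <- tapply(mainstem$temp[, 1], day, mean)
  as.integer(as.numeric(names(dm))[which.max(dm)] * 24 + 12)
}

## Mainstem temperature at arbitrary rkm positions for a block of hours.
## Linear in rkm between reservoir nodes, constant beyond the end nodes.
mainstem_at <- function(scape, position, hour_index) {
  temp <- scape$mainstem$temp
  nodes <- scape$mainstem$node_rkm
  if (ncol(temp) == 1 || isTRUE(scape$uniform_mainstem)) {
    v <- temp[hour_index, 1]
    if (length(v) == 1L && length(position) > 1L)
      v <- rep(v, length(position))
    return(v)
  }
  k <- findInterval(position, nodes)
  k <- pmin(pmax(k, 1L), length(nodes) - 1L)
  w <- (position - nodes[k]) / (nodes[k + 1] - nodes[k])
  w <- pmin(pmax(w, 0), 1)
  t_lo <- temp[cbind(hour_index, k)]
  t_hi <- temp[cbind(hour_index, k + 1L)]
  (1 - w) * t_lo + w * t_hi
}

hour_to_index <- function(scape, hour) {
  idx <- hour - scape$hours[1] + 1L
  if (any(idx < 1L | idx > length(scape$hours)))
    stop("hour outside the simulation window", call. = FALSE)
  idx
}

#' Look up a temperature in a thermalscape
#'
#' Mainstem temperatures are interpolated linearly in rkm between reservoir
#' nodes at the nearest hour; refuge temperatures are looked up by refuge id
#' with `mode` selecting the tributary (holding) or plume (entering/exiting)
#' component.
#'
#' @param scape A `thermalscape`.
#' @param position Either a numeric rkm inside the corridor or a refuge id
#'   string.
#' @param hour Calendar hour inside the simulation window.
#' @param mode For refuge lookups, `"tributary"` or `"plume"`.
#' @return Temperature (degree C).
#' @export
temperature_at <- function(scape, position, hour,
                           mode = c("mainstem", "tributary", "plume")) {
  mode <- match.arg(mode)
  idx <- hour_to_index(scape, as.integer(round(hour)))
  if (is.character(position)) {
    j <- match(position, scape$refuges$id)
    if (is.na(j)) stop("unknown refuge id: ", position, call. = FALSE)
    trib <- unname(scape$trib[idx, j])
    if (mode == "tributary" || mode == "mainstem") return(trib)
    main <- unname(mainstem_at(scape, scape$refuges$position[j], idx))
    return(plume_temperature(trib, main, scape$mixing_fraction))
  }
  if (position < scape$map$origin_rkm || position > scape$map$terminus_rkm)
    stop("position outside the corridor", call. = FALSE)
  unname(mainstem_at(scape, position, idx))
}

#' Apply refuge qualification criteria
#'
#' Keeps candidate refuges whose mean August discharge exceeds the minimum
#' and whose tributary is at least `cooler_by` degree C colder than the
#' mainstem at the refuge position during at least one hour of the window.
#'
#' @param candidates Candidate refuge table (rows of a river map's
#'   `refuges`).
#' @param scape A `thermalscape` carrying the mainstem field and the
#'   candidate tributary series (its `trib` columns must cover the
#'   candidates).
#' @param criteria [qualification_criteria()].
#' @param .ids Internal: return ids instead of the subset table.
#' @return The qualifying subset of `candidates` (or their ids).
#' @export
qualify_refuges <- function(candidates, scape,
                            criteria = qualification_criteria(),
                            .ids = FALSE) {
  if (nrow(candidates) && !length(scape$hours))
    stop("thermalscape has no hours overlapping the window", call. = FALSE)
  keep <- logical(nrow(candidates))
  for (j in seq_len(nrow(candidates))) {
    id <- candidates$id[j]
    trib <- scape$trib[, id]
    main <- mainstem_at(scape, candidates$position[j],
                        seq_along(scape$hours))
    keep[j] <- candidates$mean_aug_discharge[j] > criteria$min_discharge &&
      any(trib <= main - criteria$cooler_by)
  }
  if (.ids) candidates$id[keep] else candidates[keep, , drop = FALSE]
}

#' Warm a thermalscape
#'
#' Shifts the mainstem field by `+delta` degree C everywhere.  Plumes are
#' recomputed from the warmed mainstem wherever they are evaluated; by
#' default the tributary source water is left unchanged
#' (`warm_tributaries = TRUE` also shifts refuge tributaries).
#'
#' @param scape A `thermalscape`.
#' @param delta Warming in degree C (>= 0).
#' @param warm_tributaries Also warm refuge tributary series?
#' @return The warmed `thermalscape`, relabelled `climate = "future"` when
#'   `delta > 0`.
#' @export
apply_warming <- function(scape, delta, warm_tributaries = FALSE) {
  stopifnot(delta >= 0)
  scape$mainstem$temp <- scape$mainstem$temp + delta
  if (warm_tributaries) scape$trib <- scape$trib + delta
  scape$warming_delta <- scape$warming_delta + delta
  if (delta > 0) scape$scenario$climate <- "future"
  scape$peak_hour <- peak_hour_of(scape$mainstem)
  scape
}

#' Remove all cold-water refuges from a thermalscape
#'
#' Empties the refuge list without touching the mainstem field; idempotent.
#'
#' @param scape A `thermalscape`.
#' @return The refuge-free `thermalscape` (`cwr = FALSE`).
#' @export
remove_refuges <- function(scape) {
  scape$refuges <- scape$refuges[0, , drop = FALSE]
  scape$trib <- scape$trib[, 0, drop = FALSE]
  scape$scenario$cwr <- FALSE
  scape
}

scenario_label <- function(scape) {
  paste0(scape$scenario$climate, "_",
         if (scape$scenario$cwr) "cwr" else "nocwr")
}

#' @export
print.thermalscape <- function(x, ...) {
  cat("Thermalscape [", scenario_label(x), "]:",
      length(x$hours), "hourly steps,",
      ncol(x$mainstem$temp), "reservoirs,",
      nrow(x$refuges), "refuges\n")
  cat("  mainstem range:",
      sprintf("%.1f-%.1f", min(x$mainstem$temp), max(x$mainstem$temp)),
      "degree C; peak daily mean at hour", x$peak_hour,
      sprintf("(doy %.0f)\n", x$peak_hour / 24))
  invisible(x)
}
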