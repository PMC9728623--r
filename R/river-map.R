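# The default river map: lower Columbia corridor, Bonneville Dam (rkm 235)
# to the Snake River confluence (rkm 537), three hydropower dams and nine
# cold-water refuges.  Refuge names, volumes and temperature targets are the
# published survey values; positions, discharges and dam positions are
# fixture constants (not printed in the source material) and can be
# overridden through the map object.

.DEFAULT_REFUGES <- data.frame(
  id = c("eagle", "rock", "herman", "wind", "little_white_salmon",
         "white_salmon", "klickitat", "deschutes", "umatilla"),
  name = c("Eagle Creek", "Rock Creek", "Herman Creek", "Wind River",
           "Little White Salmon River", "White Salmon River",
           "Klickitat River", "Deschutes River", "Umatilla River"),
  position = c(238, 242, 245, 250, 261, 270, 290, 328, 465),
  volume = c(2988, 1708, 169698, 105220, 1101126, 153529, 222029,
             880124, 46299),
  mean_aug_discharge = c(0.5, 0.4, 1.5, 10, 30, 20, 40, 170, 5),
  t_mean = c(13.9, 15.4, 10.6, 13.2, 8.0, 11.6, 13.8, 16.8, 18.4),
  t_lo = c(7.8, 7.8, 6.3, 7.3, 6.3, 6.9, 6.7, 11.1, 9.5),
  t_hi = c(20.3, 20.9, 13.4, 17.1, 10.1, 14.3, 18.5, 21.5, 24.1),
  stringsAsFactors = FALSE
)

.DEFAULT_DAMS <- data.frame(
  name = c("The Dalles", "John Day", "McNary"),
  position = c(308, 347, 470),
  stringsAsFactors = FALSE
)

#' Default river map of the migration corridor
#'
#' Returns the fixed fixture describing the simulated corridor: origin at
#' rkm 235 (Bonneville Dam), terminus at rkm 537 (Snake River confluence),
#' three dams, and the nine surveyed cold-water refuges with their volumes
#' and July-November temperature targets.  Seven refuges sit in the first
#' reservoir, one in the second, one in the third.
#'
#' @return A list of class `river_map` with elements `origin_rkm`,
#'   `terminus_rkm`, `dams` (data frame: name, position),
#'   `refuges` (data frame: id, name, position, volume, mean_aug_discharge,
#'   t_mean, t_lo, t_hi), and `reservoir_boundaries` (rkm vector delimiting
#'   the four reservoirs).
#' @examples
#' map <- default_river_map()
#' nrow(map$refuges)                       # 9
#' map$terminus_rkm - map$origin_rkm       # 302
#' @export
default_river_map <- function() {
  map <- list(origin_rkm = 235,
              terminus_rkm = 537,
              dams = .DEFAULT_DAMS,
              refuges = .DEFAULT_REFUGES,
              reservoir_boundaries = c(235, 308, 347, 470, 537))
  class(map) <- "river_map"
  validate_river_map(map)
  map
}

validate_river_map <- function(map) {
  stopifnot(inherits(map, "river_map"))
  if (any(map$dams$position <= map$origin_rkm) ||
      any(map$dams$position >= map$terminus_rkm))
    stop("every dam must lie strictly inside the corridor", call. = FALSE)
  if (is.unsorted(map$dams$position, strictly = TRUE))
    stop("dams must be ordered upstream", call. = FALSE)
  if (any(map$refuges$position < map$origin_rkm) ||
      any(map$refuges$position > map$terminus_rkm))
    stop("refuges must lie inside the corridor", call. = FALSE)
  if (any(map$refuges$volume <= 0))
    stop("refuge volumes must be positive", call. = FALSE)
  if (any(map$refuges$t_lo > map$refuges$t_hi))
    stop("refuge temperature range inverted", call. = FALSE)
  invisible(map)
}

#' @export
print.river_map <- function(x, ...) {
  cat("River corridor map:", x$origin_rkm, "-", x$terminus_rkm, "rkm (",
      x$terminus_rkm - x$origin_rkm, "rkm )\n")
  cat("  dams:   ", paste0(x$dams$name, " (", x$dams$position, ")",
                           collapse = ", "), "\n")
  cat("  refuges:", nrow(x$refuges), "cold-water refuges,",
      "volumes", format(min(x$refuges$volume), big.mark = ","), "-",
      format(max(x$refuges$volume), big.mark = ","), "m3\n")
  invisible(x)
}
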