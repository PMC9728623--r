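# The hourly individual-based engine.  State lives in an environment of
# parallel vectors (one slot per fish); `.advance_hour()` is the single
# code path for both the population run (`run_scenario`) and the one-fish
# step operation (`step_fish`).

.MODE <- c(pre = 0L, migrating = 1L, refuge_enter = 2L, refuge_hold = 3L,
           refuge_exit = 4L, tailrace = 5L, fishway = 6L, arrived = 7L,
           dead_acute = 8L, dead_energy = 9L)
.MODE_NAMES <- names(.MODE)
.IN_REFUGE <- .MODE[c("refuge_enter", "refuge_hold", "refuge_exit")]
.ACTIVE <- 1L:6L

#' Scenario configuration
#'
#' Bundles every parameter of one simulated scenario: species cohort,
#' thermalscape labels (current/future climate, refuges available or not),
#' population size, master seed, and all sub-model parameter blocks.  Two
#' runs with equal configs are identical.
#'
#' @param species `"steelhead"` or `"chinook"`.
#' @param climate `"current"` or `"future"` (future shifts the mainstem by
#'   `warming_delta`).
#' @param cwr Are cold-water refuges available?
#' @param n_fish Number of simulated fish.
#' @param seed Master seed; drives cohort, temperature fields, calibration
#'   and all per-fish behaviour streams.
#' @param warming_delta Future-scenario mainstem warming (degree C).
#' @param warm_tributaries Also warm refuge tributaries in the future
#'   scenario?
#' @param map,mainstem,cohort,bio,acute,behavior,criteria Parameter blocks
#'   (see the respective constructors); `cohort = NULL` uses the species
#'   defaults.
#' @param mixing_fraction Plume mixing fraction.
#' @param dam_template [dam_spec()] replicated at each dam position after
#'   calibration.
#' @param passage_target_h,passage_tolerance Median passage calibration
#'   target and relative tolerance.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(species = "steelhead",
                            climate = c("current", "future"),
                            cwr = TRUE,
                            n_fish = 1000,
                            seed = 1,
                            warming_delta = 1,
                            warm_tributaries = TRUE,
                            map = default_river_map(),
                            mainstem = mainstem_params(),
                            cohort = NULL,
                            bio = bioenergetics_params(),
                            acute = acute_survival_params(),
                            behavior = behavior_params(),
                            criteria = qualification_criteria(),
                            mixing_fraction = 0.7,
                            dam_template = dam_spec(),
                            passage_target_h = 19,
                            passage_tolerance = 0.15) {
  climate <- match.arg(climate)
  if (is.null(cohort)) cohort <- cohort_params(species)
  cfg <- list(species = species, climate = climate, cwr = cwr,
              n_fish = as.integer(n_fish), seed = as.integer(seed),
              warming_delta = warming_delta,
              warm_tributaries = warm_tributaries,
              map = map, mainstem = mainstem, cohort = cohort, bio = bio,
              acute = acute, behavior = behavior, criteria = criteria,
              mixing_fraction = mixing_fraction,
              dam_template = dam_template,
              passage_target_h = passage_target_h,
              passage_tolerance = passage_tolerance)
  class(cfg) <- "scenario_config"
  if (cfg$n_fish < 0) stop("n_fish must be non-negative", call. = FALSE)
  cfg
}

## Build the thermalscape a config implies (current scape transformed by
## climate / refuge labels).  Paired scenarios built from the same
## (map, mainstem, seed) share the identical current field.
config_scape <- function(config, base = NULL) {
  scape <- base %||% build_thermalscape(config$map, config$mainstem,
                                        seed = config$seed,
                                        criteria = config$criteria,
                                        mixing_fraction = config$mixing_fraction)
  if (config$climate == "future")
    scape <- apply_warming(scape, config$warming_delta,
                           config$warm_tributaries)
  if (!config$cwr) scape <- remove_refuges(scape)
  scape
}

#' Instantiate the calibrated dams of a scenario
#'
#' Replicates a (calibrated) dam template at each dam position of the
#' config's river map; when no template is supplied, runs
#' [calibrate_passage()] first with a seed derived from the config seed.
#'
#' @param config A [scenario_config()].
#' @param calibrated Optional pre-calibrated [dam_spec()] template.
#' @return A list of `dam_spec`s, one per dam.
#' @export
config_dams <- function(config, calibrated = NULL) {
  tmpl <- calibrated %||% calibrate_passage(config$dam_template,
                                            config$passage_target_h,
                                            config$passage_tolerance,
                                            seed = sub_seed(config$seed, 909))
  lapply(seq_len(nrow(config$map$dams)), function(d) {
    dam <- tmpl
    dam$position <- config$map$dams$position[d]
    dam$name <- config$map$dams$name[d]
    dam
  })
}

## Per-fish pre-drawn uniform streams: one seeded sub-stream per fish, so a
## fish's randomness is invariant to n_fish.  Layout per fish: H refuge
## decision draws, H advance/hold draws, nblk mortality draws, 40 residence
## draws, 9 dam draws.
.fish_streams <- function(seed, n, H) {
  nblk <- ceiling(H / 24) + 1L
  total <- 2L * H + nblk + 40L + 9L
  U <- matrix(0, nrow = max(n, 0), ncol = total)
  for (i in seq_len(n))
    U[i, ] <- with_seed(sub_seed(seed, 1000000 + i), stats::runif(total))
  list(act = U[, seq_len(H), drop = FALSE],
       adv = U[, H + seq_len(H), drop = FALSE],
       mort = U[, 2L * H + seq_len(nblk), drop = FALSE],
       res = U[, 2L * H + nblk + seq_len(40L), drop = FALSE],
       dam = U[, 2L * H + nblk + 40L + seq_len(9L), drop = FALSE])
}

## Initialise the engine state environment.
.init_state <- function(cohort, scape, dams, config, trace = FALSE) {
  st <- new.env(parent = emptyenv())
  n <- nrow(cohort)
  H <- length(scape$hours)
  h0 <- scape$hours[1]
  hEnd <- scape$hours[H]
  st$n <- n; st$H <- H; st$h0 <- h0
  st$mass <- cohort$mass_g
  st$energy0 <- cohort$mass_g * config$bio$initial_energy_density
  st$energy <- st$energy0
  st$decrement <- numeric(n)
  st$pos <- rep(config$map$origin_rkm, n)
  st$speed_kmh <- cohort$swim_speed_kmd / 24
  st$propensity <- cohort$propensity
  st$entry <- pmin(pmax(cohort$entry_hour, h0), hEnd - 1L)
  st$target <- cohort$target_arrival_hour
  st$mode <- rep(.MODE[["pre"]], n)
  st$refuge_j <- rep(NA_integer_, n)
  st$residence_left <- numeric(n)
  st$tail_left <- integer(n)
  st$fwy_left <- integer(n)
  st$next_dam <- rep(1L, n)
  st$nhours <- integer(n)
  st$roll_sum <- numeric(n)
  st$n_entries <- integer(n)
  st$hours_in_refuge <- integer(n)
  st$refusals <- integer(n)
  st$arrival <- rep(NA_integer_, n)
  st$death_hour <- rep(NA_integer_, n)
  ## 24-h ring buffer for the rolling mean; full exposure is assembled
  ## from the per-hour logs after the run (avoids an O(n x H) copy per
  ## hour of the hot loop).
  st$ring <- matrix(0, nrow = n, ncol = 24)
  st$expo_act <- vector("list", H)
  st$expo_tt <- vector("list", H)
  nref <- nrow(scape$refuges)
  st$occ <- integer(nref)
  st$dam_pos <- vapply(dams, `[[`, numeric(1), "position")
  st$cap <- refuge_capacity(scape$refuges$volume,
                            config$behavior$max_density_fish_m3)
  st$occ_trace <- matrix(0L, nrow = H, ncol = nref,
                         dimnames = list(NULL, scape$refuges$id))
  st$inref_trace <- integer(H)
  st$trace <- trace
  if (trace) {
    st$energy_log <- vector("list", H)
    st$mode_log <- vector("list", H)
  }
  st
}

## One hour of simulation for every fish.  `h` is the row index into the
## scape's hour grid; mutates `st` in place.
.advance_hour <- function(st, h, scape, dams, config, U) {
  bp <- config$behavior; bio <- config$bio; ac <- config$acute
  ch <- scape$hours[h]
  md <- st$mode

  pre <- which(md == .MODE[["pre"]] & st$entry < ch)
  if (length(pre)) { st$mode[pre] <- .MODE[["migrating"]]; md <- st$mode }

  act <- which(md >= 1L & md <= 6L)
  if (!length(act)) return(invisible(FALSE))

  ref_pos <- scape$refuges$position
  nref <- length(ref_pos)

  ## --- exposure temperatures ------------------------------------------
  tt <- numeric(length(act))
  m_act <- md[act]
  open_water <- m_act == 1L | m_act == 5L | m_act == 6L
  if (any(open_water)) {
    i <- act[open_water]
    tt[open_water] <- mainstem_at(scape, st$pos[i], rep(h, length(i)))
  }
  holding <- m_act == 3L
  if (any(holding))
    tt[holding] <- scape$trib[h, st$refuge_j[act[holding]]]
  transit <- m_act == 2L | m_act == 4L
  if (any(transit)) {
    i <- act[transit]
    j <- st$refuge_j[i]
    main_r <- mainstem_at(scape, ref_pos[j], rep(h, length(i)))
    tt[transit] <- plume_temperature(scape$trib[h, j], main_r,
                                     scape$mixing_fraction)
  }

  st$expo_act[[h]] <- act
  st$expo_tt[[h]] <- tt
  r <- (h - 1L) %% 24L + 1L
  old <- numeric(length(act))
  full <- st$nhours[act] >= 24L
  if (any(full)) old[full] <- st$ring[act[full], r]
  st$ring[act, r] <- tt
  st$roll_sum[act] <- st$roll_sum[act] + tt - old
  st$nhours[act] <- st$nhours[act] + 1L
  in_ref_now <- act[m_act %in% 2:4]
  st$hours_in_refuge[in_ref_now] <- st$hours_in_refuge[in_ref_now] + 1L

  ## --- energy ----------------------------------------------------------
  activity <- rep(bio$act_migrating, length(act))
  activity[m_act == 3L] <- bio$act_refuge
  factor <- rep(1, length(act))
  factor[m_act == 5L] <- bio$tailrace_factor
  factor[m_act == 6L] <- bio$fishway_factor
  dec <- respiration_kjh(st$mass[act], tt, activity, bio) * factor
  st$energy[act] <- st$energy[act] - dec
  st$decrement[act] <- st$decrement[act] + dec
  free_refuge <- function(i) {
    j <- st$refuge_j[i]
    j <- j[!is.na(j)]
    if (length(j)) {
      tabj <- tabulate(j, nbins = nref)
      st$occ <- st$occ - tabj
    }
    st$refuge_j[i] <- NA_integer_
  }

  ## --- energetic mortality --------------------------------------------
  dead_e <- act[st$energy[act] / st$mass[act] < bio$lethal_energy_density]
  if (length(dead_e)) {
    free_refuge(dead_e)
    st$mode[dead_e] <- .MODE[["dead_energy"]]
    st$death_hour[dead_e] <- ch
  }

  ## --- acute mortality (per completed 24-h block) ----------------------
  alive <- act[!(act %in% dead_e)]
  blk <- alive[st$nhours[alive] %% 24L == 0L & st$nhours[alive] >= 24L]
  if (length(blk)) {
    tbar <- st$roll_sum[blk] / 24
    hz <- tbar > ac$hazard_onset
    if (any(hz)) {
      cand <- blk[hz]
      p_die <- 1 - acute_survival_probability(tbar[hz], ac)
      block_idx <- st$nhours[cand] %/% 24L
      u <- U$mort[cbind(cand, block_idx)]
      dead_a <- cand[u < p_die]
      if (length(dead_a)) {
        free_refuge(dead_a)
        st$mode[dead_a] <- .MODE[["dead_acute"]]
        st$death_hour[dead_a] <- ch
        alive <- alive[!(alive %in% dead_a)]
      }
    }
  }

  ## --- mode transitions -------------------------------------------------
  md <- st$mode
  i <- alive[md[alive] == 5L]        # tailrace
  if (length(i)) {
    st$tail_left[i] <- st$tail_left[i] - 1L
    done <- i[st$tail_left[i] <= 0L]
    st$mode[done] <- .MODE[["fishway"]]
  }
  i <- alive[md[alive] == 6L]        # fishway
  if (length(i)) {
    st$fwy_left[i] <- st$fwy_left[i] - 1L
    done <- i[st$fwy_left[i] <= 0L]
    st$mode[done] <- .MODE[["migrating"]]
  }
  i <- alive[md[alive] == 2L]        # finished the inbound detour
  st$mode[i] <- .MODE[["refuge_hold"]]
  i <- alive[md[alive] == 4L]        # finished the outbound detour
  if (length(i)) {
    free_refuge(i)
    st$mode[i] <- .MODE[["migrating"]]
  }
  i <- alive[md[alive] == 3L]        # holding
  if (length(i)) {
    st$residence_left[i] <- st$residence_left[i] - 1
    mot <- motivation_factor(ch, st$target[i], bp)
    leave <- i[st$residence_left[i] <= 0 | mot >= bp$refuge_exit_motivation]
    st$mode[leave] <- .MODE[["refuge_exit"]]
  }

  mig <- alive[md[alive] == 1L]      # migrating: decide, then move
  if (length(mig)) {
    enter <- logical(length(mig))
    if (nref > 0L) {
      ## candidate refuge: the coldest currently-cool tributary at or
      ## upstream of the fish within the detection window
      k <- integer(length(mig))
      best_t <- rep(Inf, length(mig))
      pos_mig <- st$pos[mig]
      for (j in seq_len(nref)) {
        trib_j <- scape$trib[h, j]
        main_j <- mainstem_at(scape, ref_pos[j], h)
        if (trib_j > main_j - config$criteria$cooler_by) next
        elig <- ref_pos[j] >= pos_mig &
          ref_pos[j] - pos_mig <= bp$detection_window_rkm &
          trib_j < best_t
        k[elig] <- j
        best_t[elig] <- trib_j
      }
      valid <- k > 0L
      k[!valid] <- 1L                 # placeholder index
      dist <- ref_pos[k] - pos_mig
      roll_mean <- st$roll_sum[mig] / pmax(pmin(st$nhours[mig], 24L), 1L)
      mot <- motivation_factor(ch, st$target[mig], bp)
      p <- p_enter_refuge(roll_mean, st$propensity[mig], dist, mot, bp)
      want <- valid & U$act[mig, h] < p
      room <- st$occ[k] < st$cap[k]
      refused <- want & !room
      st$refusals[mig[refused]] <- st$refusals[mig[refused]] + 1L
      enter <- want & room
      if (any(enter)) {
        ei <- mig[enter]
        jj <- k[enter]
        st$refuge_j[ei] <- jj
        st$occ <- st$occ + tabulate(jj, nbins = nref)
        st$n_entries[ei] <- st$n_entries[ei] + 1L
        ridx <- ((st$n_entries[ei] - 1L) %% 40L) + 1L
        u_res <- U$res[cbind(ei, ridx)]
        st$residence_left[ei] <-
          ceiling(pmax(bp$residence_min_h,
                       qlnorm_ms(u_res, bp$residence_mean_h,
                                 bp$residence_sd_h)))
        st$mode[ei] <- .MODE[["refuge_enter"]]
      }
    }
    stay <- mig[!enter]
    mot_stay <- motivation_factor(ch, st$target[stay], bp)
    go <- U$adv[stay, h] < pmin(1, bp$p_advance_base * mot_stay)
    held <- stay[!go]
    if (length(held)) {
      ## a held hour costs station-holding activity, not swimming activity
      refund <- respiration_kjh(st$mass[held], st$ring[held, r],
                                bio$act_migrating - bio$act_holding, bio)
      st$energy[held] <- st$energy[held] + refund
      st$decrement[held] <- st$decrement[held] - refund
    }
    mv <- stay[go]
    if (length(mv)) {
      newpos <- st$pos[mv] + st$speed_kmh[mv]
      dam_pos <- st$dam_pos
      nd <- st$next_dam[mv]
      at_dam <- if (length(dam_pos))
        nd <= length(dam_pos) & newpos >= dam_pos[pmin(nd, length(dam_pos))]
      else rep(FALSE, length(mv))
      if (any(at_dam)) {
        di <- mv[at_dam]
        for (x in seq_along(di)) {
          i2 <- di[x]
          d <- st$next_dam[i2]
          ev <- sample_dam_passage(dams[[d]], ch,
                                   u = U$dam[i2, (d - 1L) * 3L + 1:3],
                                   day_start = bp$day_start,
                                   day_end = bp$day_end)
          st$pos[i2] <- dam_pos[d]
          st$tail_left[i2] <- as.integer(ceiling(ev$tailrace_h))
          st$fwy_left[i2] <- as.integer(ceiling(ev$fishway_h))
          st$next_dam[i2] <- d + 1L
          st$mode[i2] <- .MODE[["tailrace"]]
        }
      }
      mv2 <- mv[!at_dam]
      if (length(mv2)) {
        npos <- newpos[!at_dam]
        arr <- npos >= config$map$terminus_rkm
        st$pos[mv2] <- pmin(npos, config$map$terminus_rkm)
        if (any(arr)) {
          ai <- mv2[arr]
          st$mode[ai] <- .MODE[["arrived"]]
          st$arrival[ai] <- ch
        }
      }
    }
  }

  ## --- traces -----------------------------------------------------------
  if (st$trace) {
    st$energy_log[[h]] <- st$energy[act]
    st$mode_log[[h]] <- m_act
  }
  st$occ_trace[h, ] <- st$occ
  st$inref_trace[h] <- sum(st$mode %in% .IN_REFUGE)
  invisible(TRUE)
}

## Rebuild the full n x H exposure matrix from the per-hour logs.
.assemble_exposure <- function(st) {
  m <- matrix(NA_real_, st$n, st$H)
  for (h in seq_len(st$H)) {
    a <- st$expo_act[[h]]
    if (length(a)) m[a, h] <- st$expo_tt[[h]]
  }
  m
}

#' Advance a single fish by one hour
#'
#' One-fish wrapper around the engine's hourly update, useful for
#' inspecting the mechanics: the fish's action is decided, its position and
#' energy updated, one exposure hour appended.
#'
#' @param fish A list describing one fish: `mass_g`, `energy_kj`,
#'   `position_rkm`, `mode` (a `.MODE` name such as `"migrating"`),
#'   `entry_hour`, `target_arrival_hour`, `swim_speed_kmd`, `propensity`,
#'   and optionally `exposure_log` (numeric vector of logged temperatures),
#'   `refuge_id`, `residence_left_h`.
#' @param scape A `thermalscape`.
#' @param hour Calendar hour to simulate.
#' @param config A [scenario_config()] supplying the parameter blocks.
#' @param dams List of calibrated [dam_spec()]s (default: calibrated from
#'   the config).
#' @param u Optional uniform for the behaviour decision.
#' @return The updated fish list, including the appended `exposure_log` and
#'   the hour's `action` inferred from the mode change.
#' @export
step_fish <- function(fish, scape, hour, config = scenario_config(),
                      dams = NULL, u = NULL) {
  if (is.null(dams))
    dams <- config_dams(config, calibrated = config$dam_template)
  cohort <- data.frame(fish_id = 1L, species = config$species,
                       mass_g = fish$mass_g,
                       entry_hour = fish$entry_hour %||% scape$hours[1],
                       target_arrival_hour = fish$target_arrival_hour %||%
                         (scape$hours[1] + 2000L),
                       swim_speed_kmd = fish$swim_speed_kmd %||% 20,
                       propensity = fish$propensity %||% 0)
  st <- .init_state(cohort, scape, dams, config)
  h <- hour_to_index(scape, hour)
  st$energy[1] <- fish$energy_kj %||% st$energy0[1]
  st$pos[1] <- fish$position_rkm %||% config$map$origin_rkm
  mode_in <- fish$mode %||% "migrating"
  if (mode_in == "in_refuge") mode_in <- "refuge_hold"
  st$mode[1] <- .MODE[[mode_in]]
  if (!is.null(fish$refuge_id)) {
    st$refuge_j[1] <- match(fish$refuge_id, scape$refuges$id)
    st$residence_left[1] <- fish$residence_left_h %||% 24
    st$occ[st$refuge_j[1]] <- 1L
  }
  log <- fish$exposure_log %||% numeric(0)
  nlog <- length(log)
  if (nlog) {
    last24 <- utils::tail(log, 24L)
    rows <- seq.int(h - length(last24), h - 1L)
    st$ring[1L, (rows - 1L) %% 24L + 1L] <- last24
    st$nhours[1] <- nlog
    st$roll_sum[1] <- sum(last24)
  }
  U <- .fish_streams(config$seed, 1L, st$H)
  if (!is.null(u)) U$act[1L, h] <- u
  .advance_hour(st, h, scape, dams, config, U)
  out <- fish
  out$mass_g <- st$mass[1]
  out$energy_kj <- st$energy[1]
  out$energy_density_kjg <- st$energy[1] / st$mass[1]
  out$position_rkm <- st$pos[1]
  out$mode <- .MODE_NAMES[st$mode[1] + 1L]
  out$exposure_log <- c(log, st$expo_tt[[h]][1L])
  out$hours_in_refuge <- st$hours_in_refuge[1]
  out$arrival_hour <- st$arrival[1]
  out
}

#' Run one scenario to absorption
#'
#' Simulates every fish of the configured cohort hour by hour through the
#' scenario thermalscape until arrival, death, or the end of the window
#' (remaining fish are flagged `unabsorbed`, never dropped).  Bitwise
#' reproducible: every random number is pre-drawn from per-fish seeded
#' sub-streams.
#'
#' @param config A [scenario_config()].
#' @param scape Optional prebuilt `thermalscape` (as cached by
#'   [run_experiment()]); built from the config when `NULL`.
#' @param dams Optional list of calibrated dams; calibrated from the config
#'   when `NULL`.
#' @param trace Keep full per-hour energy/mode traces (memory heavy; for
#'   diagnostics and invariant checks).
#' @return An object of class `cwr_run`: `outcomes` (one row per fish; see
#'   Details), `config`, `scenario`, `peak_hour`, `occupancy` traces,
#'   `energy_check`, `dams`, and optional `traces`.
#' @details The outcome table columns are: `fish_id`, `species`,
#'   `scenario`, `fate` (`arrived`, `dead_acute`, `dead_energy`,
#'   `unabsorbed`), `entry_hour`, `arrival_hour`, `mass_g`,
#'   `initial_energy_kj`, `final_energy_kj`, `percent_energy_used`,
#'   `dd20`, `dd21`, `dd22` (degree-days above 20/21/22 degree C, literal
#'   convention), `hours_in_refuge`, `travel_time_outside_refuge_h`,
#'   `entry_offset_from_peak_h`, `swim_speed_kmd`, `n_refuge_entries`,
#'   `refusals`.
#' @examples
#' \donttest{
#' run <- run_scenario(scenario_config("steelhead", n_fish = 25, seed = 1))
#' summary(run)
#' }
#' @export
run_scenario <- function(config, scape = NULL, dams = NULL, trace = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  scape <- config_scape(config, base = scape)
  if (is.null(dams)) dams <- config_dams(config)
  cohort <- gen_cohort(config$cohort, config$n_fish, config$seed)
  st <- .init_state(cohort, scape, dams, config, trace = trace)
  U <- .fish_streams(config$seed, st$n, st$H)
  for (h in seq_len(st$H)) {
    any_active <- .advance_hour(st, h, scape, dams, config, U)
    if (!any_active && !any(st$mode == .MODE[["pre"]])) break
  }
  fate <- rep("unabsorbed", st$n)
  fate[st$mode == .MODE[["arrived"]]] <- "arrived"
  fate[st$mode == .MODE[["dead_acute"]]] <- "dead_acute"
  fate[st$mode == .MODE[["dead_energy"]]] <- "dead_energy"
  expo <- .assemble_exposure(st)
  dd <- function(thr) {
    m <- expo
    m[is.na(m) | m <= thr] <- 0
    rowSums(m) / 24
  }
  outcomes <- data.frame(
    fish_id = cohort$fish_id,
    species = cohort$species,
    scenario = rep(scenario_label(scape), st$n),
    fate = fate,
    entry_hour = st$entry,
    arrival_hour = st$arrival,
    mass_g = st$mass,
    initial_energy_kj = st$energy0,
    final_energy_kj = st$energy,
    percent_energy_used = 100 * (st$energy0 - st$energy) / st$energy0,
    dd20 = dd(20), dd21 = dd(21), dd22 = dd(22),
    hours_in_refuge = st$hours_in_refuge,
    travel_time_outside_refuge_h = st$nhours - st$hours_in_refuge,
    entry_offset_from_peak_h = st$entry - scape$peak_hour,
    swim_speed_kmd = cohort$swim_speed_kmd,
    n_refuge_entries = st$n_entries,
    refusals = st$refusals,
    stringsAsFactors = FALSE
  )
  run <- list(outcomes = outcomes, config = config,
              scenario = scenario_label(scape),
              peak_hour = scape$peak_hour,
              hours = scape$hours,
              occupancy = list(by_refuge = st$occ_trace,
                               in_refuge_mode = st$inref_trace,
                               capacity = st$cap),
              refusals_total = sum(st$refusals),
              energy_check = data.frame(initial = st$energy0,
                                        final = st$energy,
                                        decrement_sum = st$decrement),
              dams = dams)
  if (trace) {
    energy_m <- matrix(NA_real_, st$n, st$H)
    mode_m <- matrix(NA_integer_, st$n, st$H)
    for (h in seq_len(st$H)) {
      a <- st$expo_act[[h]]
      if (length(a)) {
        energy_m[a, h] <- st$energy_log[[h]]
        mode_m[a, h] <- st$mode_log[[h]]
      }
    }
    run$traces <- list(energy = energy_m, mode = mode_m, exposure = expo)
  }
  class(run) <- "cwr_run"
  run
}
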