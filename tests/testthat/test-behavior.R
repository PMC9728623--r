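test_that("refuge entry probability obeys the decision-table structure", {
  bp <- behavior_params()
  # no thermal stress below the onset, regardless of propensity
  expect_equal(p_enter_refuge(15, 1, 1, 1, bp), 0)
  expect_equal(p_enter_refuge(bp$stress_onset, 0.5, 2, 1, bp), 0)
  # non-decreasing in the rolling 24-h mean over a grid
  grid <- seq(15, 28, by = 0.25)
  p <- p_enter_refuge(grid, 0.7, 3, 1.2, bp)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  # decreasing in distance and in motivation
  expect_gt(p_enter_refuge(23, 0.7, 1, 1, bp),
            p_enter_refuge(23, 0.7, 8, 1, bp))
  expect_gt(p_enter_refuge(23, 0.7, 3, 1, bp),
            p_enter_refuge(23, 0.7, 3, 3, bp))
  # propensity gates entry entirely
  expect_equal(p_enter_refuge(25, 0, 1, 1, bp), 0)
})

test_that("decide_action maps the decision surface onto actions", {
  bp <- behavior_params()
  ctx <- list(rolling_mean_24h = 24, refuge_dist_rkm = 2, refuge_open = TRUE,
              hour = 5000, target_hour = 8000)
  fish <- list(mode = "migrating", propensity = 1)
  expect_equal(decide_action(fish, ctx, u = 0, u_adv = 0, bp)$action,
               "enter_refuge")
  expect_equal(decide_action(fish, ctx, u = 0.999, u_adv = 0, bp)$action,
               "advance")
  expect_equal(decide_action(fish, ctx, u = 0.999, u_adv = 0.999, bp)$action,
               "hold")
  # cold water: never enters even with u = 0
  cold <- ctx; cold$rolling_mean_24h <- 15
  expect_equal(decide_action(fish, cold, u = 0, u_adv = 0, bp)$p_enter, 0)
  # holding fish exits on residence expiry or motivation
  inref <- list(mode = "in_refuge", propensity = 1, residence_left_h = 0)
  expect_equal(decide_action(inref, ctx, params = bp)$action, "exit_refuge")
  inref$residence_left_h <- 10
  expect_equal(decide_action(inref, ctx, params = bp)$action, "hold")
  late <- ctx; late$hour <- 8100
  expect_equal(decide_action(inref, late, params = bp)$action, "exit_refuge")
})

test_that("refuge capacity gates entry strictly", {
  expect_false(refuge_entry_allowed(list(occupants = 10, capacity = 10)))
  expect_true(refuge_entry_allowed(list(occupants = 0, capacity = 10)))
  expect_true(refuge_entry_allowed(list(occupants = 9, capacity = 10)))
})

test_that("refuge residence sampling matches its configured distribution", {
  bp0 <- behavior_params(residence_mean_h = 24, residence_sd_h = 0)
  expect_equal(sample_refuge_residence(bp0, u = 0.37), 24)
  bp <- behavior_params(residence_mean_h = 100, residence_sd_h = 80)
  set.seed(8)
  draws <- replicate(10000, sample_refuge_residence(bp))
  expect_lt(abs(mean(draws) - 100) / 100, 0.05)
  expect_true(all(draws > 0))
})

test_that("motivation ramps from baseline 1 to its saturation value", {
  bp <- behavior_params()
  target <- 7000
  expect_equal(motivation_factor(target - 100 * 24, target, bp), 1)
  hours <- seq(target - 60 * 24, target + 20 * 24, by = 12)
  m <- motivation_factor(hours, target, bp)
  expect_true(all(diff(m) >= 0))
  expect_equal(motivation_factor(target, target, bp), bp$motivation_max)
  expect_gte(motivation_factor(target + 500, target, bp), bp$motivation_max)
})

test_that("a single fish transits the corridor in closed form", {
  cfg <- scenario_config("steelhead", n_fish = 1, seed = 5,
                         mainstem = flat_params(15),
                         cohort = point_cohort(speed = 20),
                         behavior = behavior_params(p_advance_base = 1),
                         map = damless_map())
  run <- run_scenario(cfg, dams = list())
  o <- run$outcomes
  expect_equal(o$fate, "arrived")
  expect_equal(o$arrival_hour - o$entry_hour, ceiling(302 / 20 * 24))
  expect_equal(o$hours_in_refuge, 0)
  expect_equal(o$dd20, 0)  # 15 degree C water never exceeds 20
})

test_that("runs are bitwise reproducible and refuge-free without CWRs", {
  cfg <- scenario_config("steelhead", n_fish = 30, seed = 9)
  dams <- config_dams(cfg, calibrated = ref_dam())
  a <- run_scenario(cfg, dams = dams)
  b <- run_scenario(cfg, dams = dams)
  expect_identical(a$outcomes, b$outcomes)

  cfg_no <- scenario_config("steelhead", n_fish = 30, seed = 9, cwr = FALSE)
  r <- run_scenario(cfg_no, dams = dams)
  expect_true(all(r$outcomes$hours_in_refuge == 0))
  expect_true(all(r$outcomes$n_refuge_entries == 0))
  expect_equal(r$outcomes$travel_time_outside_refuge_h,
               ifelse(is.na(r$outcomes$arrival_hour),
                      r$outcomes$travel_time_outside_refuge_h,
                      r$outcomes$arrival_hour - r$outcomes$entry_hour))
})

test_that("per-fish results are invariant to cohort size without refuges", {
  dams <- config_dams(scenario_config(), calibrated = ref_dam())
  small <- run_scenario(scenario_config("steelhead", n_fish = 5, seed = 13,
                                        cwr = FALSE), dams = dams)
  large <- run_scenario(scenario_config("steelhead", n_fish = 12, seed = 13,
                                        cwr = FALSE), dams = dams)
  expect_identical(small$outcomes, large$outcomes[1:5, ])
})

test_that("stepping a fish applies exposure, energy and movement", {
  scape <- cached("scape1", build_thermalscape(seed = 1))
  cfg <- scenario_config("steelhead",
                         behavior = behavior_params(p_advance_base = 1))
  h <- scape$hours[2400]
  fish <- list(mass_g = 5000, energy_kj = 37500, position_rkm = 300,
               mode = "migrating", entry_hour = h - 100L,
               target_arrival_hour = h + 2000L, swim_speed_kmd = 24,
               propensity = 0)
  out <- step_fish(fish, scape, h, cfg, dams = list())
  expect_equal(out$position_rkm, 301)          # 24 km/day = 1 rkm/h
  expect_lt(out$energy_kj, fish$energy_kj)     # respiration is strictly > 0
  expect_equal(length(out$exposure_log), 1)
  expect_equal(out$exposure_log[1], temperature_at(scape, 300, h))

  # a holding fish stays put and logs the tributary temperature
  fish_r <- fish
  fish_r$mode <- "in_refuge"; fish_r$refuge_id <- "herman"
  fish_r$residence_left_h <- 48
  out_r <- step_fish(fish_r, scape, h, cfg, dams = list())
  expect_equal(out_r$position_rkm, fish$position_rkm)
  expect_equal(out_r$exposure_log[1],
               temperature_at(scape, "herman", h, mode = "tributary"))
  expect_equal(out_r$hours_in_refuge, 1)

  # reaching the terminus flips the mode to arrived
  fish_t <- fish; fish_t$position_rkm <- 536.8
  out_t <- step_fish(fish_t, scape, h, cfg, dams = list())
  expect_equal(out_t$mode, "arrived")
  expect_equal(out_t$arrival_hour, h)
})
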