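test_that("respiration follows the exponential-allometric form", {
  p <- bioenergetics_params()
  # temperature coefficient zero removes temperature dependence
  p0 <- bioenergetics_params(temp_coeff = 1e-12)
  expect_equal(respiration_kjh(3000, 10, 1, p0),
               respiration_kjh(3000, 25, 1, p0), tolerance = 1e-9)
  # functional-form identity: one degree multiplies the rate by e^rho
  for (m in c(2000, 5092, 8000))
    expect_equal(respiration_kjh(m, 21, 2, p) / respiration_kjh(m, 20, 2, p),
                 exp(p$temp_coeff))
  # oracle band computed from the chosen adult-salmonid coefficients:
  # a 5092 g fish migrating at 20 degree C burns a few hundred kJ per day
  daily <- 24 * respiration_kjh(5092, 20, p$act_migrating, p)
  expect_gt(daily, 150)
  expect_lt(daily, 450)
  expect_error(respiration_kjh(-1, 20, 1, p), "positive")
  # strictly increasing in mass and temperature
  expect_gt(respiration_kjh(5093, 20, 1, p), respiration_kjh(5092, 20, 1, p))
  expect_gt(respiration_kjh(5092, 20.1, 1, p), respiration_kjh(5092, 20, 1, p))
})

test_that("dam passage multiplies hourly energy cost by exactly 1.62 / 1.26", {
  p <- bioenergetics_params()
  fish <- list(mass_g = 5000, energy_kj = 35000)
  base <- update_energy(fish, 20, 1, activity = p$act_migrating,
                        habitat_factor = 1, params = p)
  tail <- update_energy(fish, 20, 1, activity = p$act_migrating,
                        habitat_factor = p$tailrace_factor, params = p)
  fway <- update_energy(fish, 20, 1, activity = p$act_migrating,
                        habitat_factor = p$fishway_factor, params = p)
  expect_equal((fish$energy_kj - tail$energy_kj) /
                 (fish$energy_kj - base$energy_kj), 1.62)
  expect_equal((fish$energy_kj - fway$energy_kj) /
                 (fish$energy_kj - base$energy_kj), 1.26)
  # dt = 0 leaves energy unchanged
  expect_equal(update_energy(fish, 20, 0, params = p)$energy_kj,
               fish$energy_kj)
})

test_that("energy-density mortality is strict at the 4 kJ/g boundary", {
  p <- bioenergetics_params()
  expect_true(energy_mortality(list(mass_g = 1000, energy_kj = 3990), p))
  expect_false(energy_mortality(list(mass_g = 1000, energy_kj = 4010), p))
  expect_false(energy_mortality(list(mass_g = 1000, energy_kj = 4000), p))
})

test_that("acute survival curve is a bounded non-increasing logistic", {
  p <- acute_survival_params()
  expect_gte(acute_survival_probability(10, p), 0.999)
  expect_gte(acute_survival_probability(15, p), 0.999)
  expect_equal(acute_survival_probability(p$t50, p), (1 + p$floor) / 2)
  grid <- acute_survival_probability(seq(10, 30, by = 0.25), p)
  expect_true(all(diff(grid) <= 0))
  pf <- acute_survival_params(floor = 0.2)
  expect_equal(acute_survival_probability(60, pf), 0.2, tolerance = 1e-6)
})

test_that("acute mortality draws only fire above the hazard onset", {
  p <- acute_survival_params()
  cold <- list(rolling_24h_temps = rep(15, 24), mode = "migrating")
  expect_equal(apply_acute_mortality(cold, u = 0, p)$mode, "migrating")
  hot <- list(rolling_24h_temps = rep(29, 24), mode = "migrating")
  expect_equal(apply_acute_mortality(hot, u = 1, p)$mode, "migrating")
  expect_equal(apply_acute_mortality(hot, u = 0, p)$mode, "dead_acute")
  short <- list(rolling_24h_temps = rep(29, 10), mode = "migrating")
  expect_error(apply_acute_mortality(short, u = 0, p), "24")
})
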