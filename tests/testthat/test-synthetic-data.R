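test_that("noise-free mainstem series equals the pure seasonal curve", {
  p <- mainstem_params(noise_sd = 0, diurnal_amplitude = 0)
  s <- gen_mainstem_series(p, seed = 1)
  expect_equal(s$temp[, 1], seasonal_temp(p, s$hours / 24))
  dm <- daily_means(s)
  peak_day_realised <- floor(s$hours[1] / 24) + which.max(dm) - 1
  expect_equal(peak_day_realised, p$peak_day)
  expect_equal(max(s$temp), p$season_peak_temp)
})

test_that("default mainstem series respects the stated thermal envelope", {
  s <- gen_mainstem_series(mainstem_params(), seed = 1)
  dm <- daily_means(s)
  days <- floor(s$hours[1] / 24) + seq_along(dm) - 1
  jul_nov <- dm[days >= 182 & days <= 334]
  expect_true(max(jul_nov) >= 22 && max(jul_nov) <= 23.5)
  expect_true(all(jul_nov >= 15), info = "Jul-Nov daily means >= 15")
  expect_true(all(jul_nov <= 24), info = "Jul-Nov daily means <= 24")
  expect_lte(min(jul_nov), 16)   # span covers down to 16
  expect_gte(max(jul_nov), 23)   # and up to 23
  day <- floor(s$hours / 24)
  diurnal <- tapply(s$temp[, 1], day, function(x) diff(range(x)))
  expect_lt(mean(diurnal), 0.5)
})

test_that("mainstem generation is deterministic under a fixed seed", {
  a <- gen_mainstem_series(mainstem_params(), seed = 11)
  b <- gen_mainstem_series(mainstem_params(), seed = 11)
  expect_identical(a, b)
  c <- gen_mainstem_series(mainstem_params(), seed = 12)
  expect_false(identical(a$temp, c$temp))
})

test_that("refuge series hit the surveyed means and stay inside ranges", {
  scape <- build_thermalscape(seed = 1)
  sel <- scape$hours >= 182 * 24 & scape$hours < 335 * 24
  for (j in seq_len(nrow(scape$refuges))) {
    spec <- scape$refuges[j, ]
    expect_lt(abs(mean(scape$trib[sel, j]) - spec$t_mean), 0.5,
              label = paste(spec$id, "Jul-Nov mean error"))
    expect_gte(min(scape$trib[, j]), spec$t_lo - 1)
    expect_lte(max(scape$trib[, j]), spec$t_hi + 1)
  }
  # every default refuge is at some hour >= 2 degree C cooler than the
  # mainstem (all nine qualify)
  for (j in seq_len(nrow(scape$refuges))) {
    main <- scape$mainstem$temp[, 1]
    expect_true(any(scape$trib[, j] <= main - 2),
                label = paste(scape$refuges$id[j], "2-degree criterion"))
  }
})

test_that("zero-noise refuge series is the fitted seasonal curve exactly", {
  ms <- gen_mainstem_series(mainstem_params(), 1)
  spec <- default_river_map()$refuges[5, ]  # Little White Salmon
  a <- gen_refuge_series(spec, ms, seed = 1, noise_sd = 0)
  b <- gen_refuge_series(spec, ms, seed = 99, noise_sd = 0)
  expect_identical(a$temp, b$temp)   # no stochastic component left
  expect_lt(abs(mean(a$temp[ms$hours >= 182 * 24 & ms$hours < 335 * 24, 1]) -
                  8.0), 0.5)
  bad <- spec; bad$t_lo <- 12; bad$t_hi <- 6
  expect_error(gen_refuge_series(bad, ms, 1), "inverted")
})

test_that("cohort generation reproduces the printed entry distributions", {
  coh <- gen_cohort(cohort_params("steelhead"), 2000, seed = 1)
  se_mass <- 1674 / sqrt(2000)
  expect_lt(abs(mean(coh$mass_g) - 5092), 2 * se_mass)
  expect_true(all(coh$mass_g > 0))
  chin <- gen_cohort(cohort_params("chinook"), 2000, seed = 1)
  se_entry <- 6.5 / sqrt(2000)
  expect_lt(abs(mean(chin$entry_hour) / 24 - 246), 2 * se_entry)
})

test_that("cohort generation is a pure function of (params, n, seed)", {
  p <- cohort_params("chinook")
  expect_identical(gen_cohort(p, 50, 3), gen_cohort(p, 50, 3))
  expect_equal(nrow(gen_cohort(p, 0, 1)), 0)
  expect_error(gen_cohort(p, -1, 1), "non-negative")
  # per-fish sub-streams: fish i is unchanged when n grows
  a <- gen_cohort(p, 5, 3); b <- gen_cohort(p, 10, 3)
  expect_identical(a$mass_g, b$mass_g[1:5])
})

test_that("the default river map matches the surveyed corridor", {
  map <- default_river_map()
  expect_equal(nrow(map$refuges), 9)
  expect_equal(nrow(map$dams), 3)
  expect_equal(map$terminus_rkm - map$origin_rkm, 302)
  expect_equal(map$refuges$volume[map$refuges$id == "herman"], 169698)
  # 7 refuges in the first reservoir, 1 in the second, 1 in the third
  b <- map$reservoir_boundaries
  counts <- table(cut(map$refuges$position, b, labels = FALSE))
  expect_equal(as.integer(counts[1:3]), c(7L, 1L, 1L))
  expect_true(all(map$dams$position > map$origin_rkm &
                    map$dams$position < map$terminus_rkm))
})
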