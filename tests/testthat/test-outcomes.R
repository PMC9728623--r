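test_that("degree-days follow the stated accumulation rules", {
  expect_equal(degree_days(rep(19.9, 24), 20), 0)
  expect_equal(degree_days(rep(21, 24), 20), 21)            # 24*21/24
  expect_equal(degree_days(rep(21, 24), 20, "exceedance"), 1)
  expect_error(degree_days(numeric(0), 20), "empty")
  # brute-force oracle on a random series, both conventions
  set.seed(21)
  x <- runif(200, 15, 26)
  lit <- 0; exc <- 0
  for (v in x) if (v > 21) { lit <- lit + v; exc <- exc + (v - 21) }
  expect_equal(degree_days(x, 21), lit / 24)
  expect_equal(degree_days(x, 21, "exceedance"), exc / 24)
})

test_that("percent energy used is the normalised depletion", {
  expect_equal(percent_energy_used(40000, 30000), 25)
  expect_equal(percent_energy_used(1234, 1234), 0)
  expect_equal(percent_energy_used(5000, 0), 100)
  expect_error(percent_energy_used(100, 150), "exceeds")
})

test_that("exceedance curves are right-continuous reverse CDFs", {
  f <- exceedance_curve(c(1, 2, 3))
  expect_equal(f(1.5), 2 / 3)
  expect_equal(f(0.999), 1)
  expect_equal(f(3), 0)
  z <- exceedance_curve(rep(0, 5))
  expect_equal(z(0), 0)
  expect_equal(z(-1e-9), 1)
})

test_that("population summary uses the documented percentile convention", {
  tab <- data.frame(fate = rep("arrived", 4),
                    percent_energy_used = c(10, 20, 30, 40),
                    arrival_hour = c(100, 200, 300, 400) + 6000,
                    hours_in_refuge = 0, n_refuge_entries = 0)
  s <- population_summary(tab)
  expect_equal(s$p25_pct_energy, 17.5)  # linear interpolation
  expect_equal(s$acute_mortality_pct, 0)
  expect_equal(s$energy_mortality_pct, 0)
  const <- tab; const$percent_energy_used <- rep(12, 4)
  sc <- population_summary(const)
  expect_equal(sc$sd_pct_energy, 0)
  expect_equal(sc$p25_pct_energy, 12)
  expect_equal(sc$p75_pct_energy, 12)
  # duplicating the table leaves means and percentiles unchanged
  s2 <- population_summary(rbind(tab, tab))
  expect_equal(s2$mean_pct_energy, s$mean_pct_energy)
  expect_equal(s2$p25_pct_energy, s$p25_pct_energy)
  expect_error(population_summary(tab[1, ]), "at least 2")
})

test_that("the energy-conserving threshold is the 25th percentile", {
  tab <- data.frame(fate = rep("arrived", 10),
                    percent_energy_used = seq(10, 100, by = 10))
  expect_equal(energy_conserving_threshold(tab), 32.5)
  expect_equal(energy_conserving_threshold(tab, 50), 55)
})

test_that("phenotype-space HDR areas behave like nested coverage regions", {
  set.seed(42)
  x <- runif(20000, 0, 10); y <- runif(20000, 0, 4)
  pts <- cbind(x, y)
  a95 <- phenotype_space_area(pts, 95)
  expect_lt(abs(a95 - 0.95 * 40) / (0.95 * 40), 0.15)
  a50 <- phenotype_space_area(pts, 50)
  a90 <- phenotype_space_area(pts, 90)
  expect_lte(a50, a90)
  expect_lte(a90, a95)
  # invariance to point order
  perm <- sample(nrow(pts))
  expect_equal(phenotype_space_area(pts[perm, ], 95), a95)
  # degenerate cloud collapses to the documented one-cell lower bound
  same <- cbind(rep(1, 20), rep(2, 20))
  expect_equal(phenotype_space_area(same, 95), 1)
  expect_error(phenotype_space_area(pts[1:5, ], 95), "at least 10")
})

test_that("space contraction is the signed relative area change", {
  expect_equal(space_contraction(100, 77), 23)
  expect_equal(space_contraction(5, 5), 0)
  expect_equal(space_contraction(100, 110), -10)
  expect_error(space_contraction(0, 1))
})

test_that("arrival densities are normalised smoothed histograms", {
  tab <- data.frame(fate = c("arrived", "arrived", "dead_acute"),
                    arrival_hour = c(6000, 6480, NA))
  d <- arrival_density(tab, bandwidth = 2)
  expect_equal(sum(d$y) * diff(d$x[1:2]), 1, tolerance = 1e-3)
  one <- arrival_density(tab[1, ], bandwidth = 2)
  expect_equal(one$x[which.max(one$y)], 250, tolerance = 0.5)  # doy 250
  expect_error(arrival_density(data.frame(fate = "dead_acute",
                                          arrival_hour = NA)), "no arrivals")
})
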