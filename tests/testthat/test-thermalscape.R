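test_that("plume mixing is the stated linear model and stays bounded", {
  expect_equal(plume_temperature(12, 20, 1.0), 12)
  expect_equal(plume_temperature(12, 20, 0.0), 20)
  expect_equal(plume_temperature(12, 20, 0.5), 16)
  expect_error(plume_temperature(12, 20, 1.2), "mixing_fraction")
  set.seed(1)
  tt <- runif(500, 5, 15); tm <- runif(500, 15, 25); f <- runif(500)
  pl <- plume_temperature(tt, tm, f)
  expect_true(all(pl >= pmin(tt, tm) - 1e-12 & pl <= pmax(tt, tm) + 1e-12))
})

test_that("refuge qualification applies both criteria and is monotone", {
  scape <- cached("scape1", build_thermalscape(seed = 1))
  cand <- scape$map$refuges
  expect_equal(nrow(qualify_refuges(cand, scape)), 9)

  low_flow <- cand
  low_flow$mean_aug_discharge[1] <- 0.2
  kept <- qualify_refuges(low_flow, scape)
  expect_false("eagle" %in% kept$id)

  # a tributary everywhere exactly 1 degree C below the mainstem never
  # meets the 2-degree criterion
  warm <- scape
  warm$trib[, "eagle"] <- warm$mainstem$temp[, 1] - 1
  expect_false("eagle" %in% qualify_refuges(cand, warm)$id)

  # relaxing either criterion never drops a previously qualified refuge
  strict <- qualify_refuges(cand, scape, qualification_criteria(0.28, 2.0))
  relaxed <- qualify_refuges(cand, scape, qualification_criteria(0.1, 1.0))
  expect_true(all(strict$id %in% relaxed$id))
})

test_that("warming shifts the mainstem field by exactly delta", {
  scape <- cached("scape1", build_thermalscape(seed = 1))
  w0 <- apply_warming(scape, 0)
  expect_equal(w0$mainstem$temp, scape$mainstem$temp)
  w1 <- apply_warming(scape, 1)
  expect_equal(w1$mainstem$temp, scape$mainstem$temp + 1)
  expect_equal(w1$trib, scape$trib)  # tributaries untouched by default
  # linear mixing: plume shifts by (1 - fraction) * delta
  h <- scape$hours[100]
  p0 <- temperature_at(scape, "herman", h, mode = "plume")
  p1 <- temperature_at(w1, "herman", h, mode = "plume")
  expect_equal(p1 - p0, (1 - scape$mixing_fraction) * 1)
  wt <- apply_warming(scape, 1, warm_tributaries = TRUE)
  expect_equal(wt$trib, scape$trib + 1)
})

test_that("refuge removal empties the refuge list and nothing else", {
  scape <- cached("scape1", build_thermalscape(seed = 1))
  bare <- remove_refuges(scape)
  expect_equal(nrow(bare$refuges), 0)
  expect_identical(remove_refuges(bare), bare)  # idempotent
  set.seed(2)
  pos <- runif(100, 235, 537)
  hrs <- sample(scape$hours, 100)
  for (k in 1:100)
    expect_identical(temperature_at(bare, pos[k], hrs[k]),
                     temperature_at(scape, pos[k], hrs[k]))
})

test_that("warming commutes with refuge removal", {
  scape <- cached("scape1", build_thermalscape(seed = 1))
  a <- remove_refuges(apply_warming(scape, 1))
  b <- apply_warming(remove_refuges(scape), 1)
  expect_equal(a$mainstem$temp, b$mainstem$temp)
  expect_equal(nrow(a$refuges), nrow(b$refuges))
})

test_that("temperature lookup interpolates and resolves refuge modes", {
  flat <- flat_scape(21)
  expect_equal(temperature_at(flat, 300, flat$hours[50]), 21)
  expect_equal(temperature_at(flat, 530, flat$hours[5000]), 21)
  expect_error(temperature_at(flat, 300, flat$hours[1] - 5), "window")
  expect_error(temperature_at(flat, 100, flat$hours[1]), "corridor")

  # refuge lookups: tributary vs plume at the same hour
  scape <- cached("scape1", build_thermalscape(seed = 1))
  h <- scape$hours[2000]
  trib <- temperature_at(scape, "herman", h, mode = "tributary")
  j <- match("herman", scape$refuges$id)
  expect_equal(trib, unname(scape$trib[2000, j]))
  plume <- temperature_at(scape, "herman", h, mode = "plume")
  main <- temperature_at(scape, scape$refuges$position[j], h)
  expect_equal(plume,
               scape$mixing_fraction * trib + (1 - scape$mixing_fraction) * main)

  # linear interpolation between reservoir nodes
  grad <- build_thermalscape(params = mainstem_params(noise_sd = 0,
                                                      diurnal_amplitude = 0,
                                                      reach_cooling_gradient = 0.01),
                             seed = 1)
  nodes <- grad$mainstem$node_rkm
  mid <- (nodes[1] + nodes[2]) / 2
  h <- grad$hours[1000]
  t1 <- temperature_at(grad, nodes[1], h)
  t2 <- temperature_at(grad, nodes[2], h)
  expect_equal(temperature_at(grad, mid, h), (t1 + t2) / 2)
})

test_that("temperature series round-trip through the delimited format", {
  scape <- cached("scape1", build_thermalscape(seed = 1))
  path <- tempfile(fileext = ".tsv")
  sub <- list(hours = scape$hours[1:48],
              temp = scape$trib[1:48, 1:2, drop = FALSE],
              ids = colnames(scape$trib)[1:2], node_rkm = NULL)
  class(sub) <- "cwr_series"
  write_temperature_series(sub, path)
  back <- read_temperature_series(path)
  expect_equal(back$hours, sub$hours)
  expect_equal(unname(back$temp), unname(sub$temp), tolerance = 1e-10)
})
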