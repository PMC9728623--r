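test_that("config validation separates errors from warnings", {
  cfg <- experiment_config(n_fish = 50, seed = 1)
  v <- validate_config(cfg)
  expect_equal(sum(v$level == "error"), 0)

  bad <- experiment_config(n_fish = -5)
  vb <- validate_config(bad)
  expect_true(any(vb$level == "error" & grepl("n_fish", vb$message)))

  warm <- experiment_config(mainstem = mainstem_params(diurnal_amplitude = 0.6))
  vw <- validate_config(warm)
  expect_true(any(vw$level == "warning" & grepl("0.5", vw$message)))
  expect_false(any(vw$level == "error"))
})

test_that("the full experiment reports all eight scenarios coherently", {
  cfg <- experiment_config(n_fish = 40, seed = 3)
  ex <- cached("experiment_small", run_experiment(cfg))
  expect_s3_class(ex, "cwr_experiment")
  expect_equal(nrow(ex$summary), 8)
  expect_setequal(unique(ex$summary$species), c("steelhead", "chinook"))
  expect_setequal(unique(ex$summary$scenario),
                  c("current_cwr", "current_nocwr", "future_cwr",
                    "future_nocwr"))
  # classification thresholds derive from the current+CWR tables only
  for (sp in c("steelhead", "chinook"))
    expect_equal(ex$thresholds[[sp]],
                 energy_conserving_threshold(
                   ex$runs[[paste0(sp, "_current_cwr")]]$outcomes))
  # scenario pairs share the same generated mainstem field
  expect_equal(length(unique(ex$manifest$mainstem_field_signature)), 2)
  # no refuge time without refuges
  no <- ex$runs[["steelhead_current_nocwr"]]$outcomes
  expect_true(all(no$hours_in_refuge == 0))
})

test_that("an experiment is a pure function of its config", {
  cfg <- experiment_config(n_fish = 15, seed = 21)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$manifest, b$manifest)
})

test_that("experiment configs round-trip through YAML", {
  cfg <- experiment_config(n_fish = 77, seed = 5,
                           behavior = behavior_params(p_base = 0.03))
  path <- tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back$n_fish, 77)
  expect_equal(back$seed, 5)
  expect_equal(back$behavior$p_base, 0.03)
  expect_equal(back$map$refuges$volume, cfg$map$refuges$volume)
  expect_equal(back$cohorts$steelhead$mass_mean, 5092)
})

test_that("experiment results serialise to the documented directory layout", {
  ex <- cached("experiment_small", run_experiment(experiment_config(n_fish = 40,
                                                                    seed = 3)))
  dir <- tempfile()
  write_experiment_results(ex, dir)
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "phenotype_report.yaml")))
  expect_equal(length(list.files(dir, pattern = "^outcomes_")), 8)
  tab <- utils::read.delim(file.path(dir, "summary.tsv"))
  expect_equal(nrow(tab), 8)
})
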