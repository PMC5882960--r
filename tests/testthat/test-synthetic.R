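test_that("the noise-free driver is an exact seasonal sinusoid", {
  ms <- simulate_environment_monthly(c(2000, 2004), phi = 0,
                                     innovation_sd = 0,
                                     seasonal_amp = c(2, 0), mean_level = 10)
  expect_equal(ms$value, 10 + 2 * sin(2 * pi * ms$month / 12),
               tolerance = 1e-12)
  # exact 12-month periodicity
  expect_equal(ms$value[1:12], ms$value[13:24])
})

test_that("driver generation is deterministic under seed and guards phi", {
  a <- simulate_environment_monthly(c(1950, 2016), 0.6, 1, c(2, 0.5), 15,
                                    seed = 99)
  b <- simulate_environment_monthly(c(1950, 2016), 0.6, 1, c(2, 0.5), 15,
                                    seed = 99)
  expect_identical(a$value, b$value)
  expect_error(simulate_environment_monthly(c(1950, 2016), 1.0, 1),
               "explosive")
  expect_error(simulate_environment_monthly(c(2000, 2000), 0.5, 1),
               "2 calendar years")
})

test_that("the driver anomaly has the configured AR(1) structure", {
  ms <- simulate_environment_monthly(c(1, 5000), 0.6, 1, c(2, 0.5), 15,
                                     seed = 31)
  anom <- deseasonalize(ms)$value
  expect_equal(first_order_autocorrelation(anom), 0.6, tolerance = 0.02)
})

test_that("shell simulation is reproducible, positive, and bookkept", {
  cfg <- default_scenario(seed = 41)
  driver <- simulate_environment_monthly(c(1940, 2016), cfg$env_phi,
                                         cfg$env_sd, cfg$seasonal_amp,
                                         cfg$env_mean, seed = 5)
  sim1 <- simulate_shell_collection(cfg, driver)
  sim2 <- simulate_shell_collection(cfg, driver)
  expect_identical(lapply(sim1$collection, `[[`, "widths"),
                   lapply(sim2$collection, `[[`, "widths"))
  expect_length(sim1$collection, 30)
  for (s in sim1$collection)
    expect_true(all(is.finite(s$widths) & s$widths > 0))
  # first measured calendar year = collection year - age + missing_first
  meta <- sim1$shells
  for (i in seq_len(nrow(meta))) {
    s <- sim1$collection[[meta$specimen_id[i]]]
    expect_equal(s$first_year,
                 meta$collection_year[i] - meta$age[i] + cfg$missing_first)
    expect_equal(max(series_years(s)), meta$collection_year[i])
  }
  expect_true(all(meta$age >= 35 & meta$age <= 72))
})

test_that("adding shells does not perturb existing substreams", {
  cfg_small <- default_scenario(seed = 41, n_shells = 10)
  cfg_big <- default_scenario(seed = 41, n_shells = 20)
  driver <- simulate_environment_monthly(c(1935, 2016), 0.6, 0.6,
                                         c(2, 0.5), 15, seed = 5)
  small <- simulate_shell_collection(cfg_small, driver)
  big <- simulate_shell_collection(cfg_big, driver)
  for (id in names(small$collection))
    expect_identical(small$collection[[id]]$widths,
                     big$collection[[id]]$widths)
})

test_that("without stochastic terms every series is its own age curve", {
  cfg <- default_scenario(seed = 41, signal_beta = 0, noise_sd = 0,
                          collection_stagger = 1)
  driver <- simulate_environment_monthly(c(1935, 2016), cfg$env_phi,
                                         cfg$env_sd, cfg$seasonal_amp,
                                         cfg$env_mean, seed = 5)
  sim <- simulate_shell_collection(cfg, driver)
  gp <- cfg$growth_params
  for (s in sim$collection) {
    ages <- seq.int(cfg$missing_first + 1, length.out = length(s$widths))
    expect_equal(s$widths, gp[["a"]] * exp(-gp[["b"]] * ages) + gp[["k"]],
                 tolerance = 1e-12)
  }
})

test_that("a driver gap inside a needed growth year is a coverage error", {
  cfg <- default_scenario(seed = 41)
  driver <- simulate_environment_monthly(c(1970, 2016), cfg$env_phi,
                                         cfg$env_sd, cfg$seasonal_amp,
                                         cfg$env_mean, seed = 5)
  expect_error(simulate_shell_collection(cfg, driver), "cover")
})

test_that("dating-error injection shifts the older portion as documented", {
  s <- increment_series("D", 1980, c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6))
  del <- inject_dating_error(s, 1983, "delete")
  expect_equal(del$first_year, 1981)
  expect_length(del$widths, 6)
  # younger values keep their dates, older values shift +1
  expect_equal(del$widths[4:6], c(1.4, 1.5, 1.6))
  expect_equal(del$widths[1:3], c(1.0, 1.1, 1.2))
  expect_equal(max(series_years(del)), 1986)

  ins <- inject_dating_error(s, 1983, "insert")
  expect_equal(ins$first_year, 1979)
  expect_length(ins$widths, 8)
  expect_equal(ins$widths[5], mean(c(1.1, 1.2, 1.3, 1.4, 1.5)))
  expect_equal(ins$widths[c(1:4, 6:8)], s$widths)

  # insert then delete at the same year restores dating and length
  restored <- inject_dating_error(ins, 1983, "delete")
  expect_equal(restored$first_year, s$first_year)
  expect_equal(restored$widths, s$widths)
  expect_error(inject_dating_error(s, 1970, "insert"), "outside")
})

test_that("scenario YAML files round-trip into configurations", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_shells: 12", "signal_beta: 0.4", "seed: 77"), path)
  cfg <- read_scenario(path)
  expect_equal(cfg$n_shells, 12L)
  expect_equal(cfg$signal_beta, 0.4)
  expect_equal(cfg$seed, 77L)
  expect_equal(cfg$age_range, c(35L, 72L))  # defaults retained
  writeLines("nonsense_field: 3", path)
  expect_error(read_scenario(path), "unknown scenario field")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(env_phi = 1), "stationary")
  expect_error(sim_config(n_shells = 0))
  expect_error(sim_config(noise_sd = -1))
  expect_error(sim_config(age_range = c(0, 10)))
})
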