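# experiment-level tests run at deliberately small scale (16-32 cells a side,
# tens of years): they exercise orchestration, metrics and sign properties,
# not the published pattern statistics

test_that("zero-length drought yields a null response", {
  p <- peat_params()
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 120)
  res <- drought_experiment(p, n_in = 1.375, drought_start = 121,
                            drought_duration = 0, post_years = 10,
                            stabilize_years = 120, config = cfg, grid = g,
                            seed = 2)
  expect_lt(res$drop, 0.01)
  expect_equal(res$recovery_years, 0)
})

test_that("a drought at baseline precipitation is a null experiment", {
  p <- peat_params()
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 60)
  res <- drought_experiment(p, n_in = 1.375, baseline_precip = 0.8,
                            drought_start = 65, drought_duration = 5,
                            drought_precip = 0.8, post_years = 10,
                            stabilize_years = 60, config = cfg, grid = g,
                            seed = 2)
  expect_lt(res$drop, 0.02)
  expect_lt(res$overshoot, 0.02)
})

test_that("nutrients accumulate while biomass drops during a real drought", {
  p <- peat_params()
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 80)
  res <- drought_experiment(p, n_in = 1.375, drought_start = 85,
                            drought_duration = 6, drought_precip = 0.05,
                            post_years = 25, stabilize_years = 80,
                            config = cfg, grid = g, seed = 3)
  y <- res$yearly
  win <- y$year >= 85 & y$year <= 90
  expect_gt(res$drop, 0.1)
  # mean N strictly increases through the drought window
  expect_true(all(diff(y$mean_N[win]) > 0))
  expect_gt(res$nutrient_peak, res$ref_N)
  # overshoot follows recovery
  expect_gt(res$overshoot, 0)
})

test_that("recovery metric depends only on the normalized series", {
  # scale invariance: recomputing recovery from a rescaled biomass series
  # must give the same answer
  rel <- c(-0.5, -0.2, 0.3, 0.15, 0.04, -0.02, 0.01, 0.02)
  recov <- function(rel, band = 0.05) {
    inside <- abs(rel) <= band
    stays <- rev(cumprod(rev(inside))) == 1
    if (!any(stays)) return(Inf)
    which(stays)[1]
  }
  for (scale in c(1, 10, 1234)) {
    series <- (1 + rel) * scale
    expect_equal(recov(series / scale - 1), 5)
  }
})

test_that("sweep inside regime 1 stays plant-free with unbracketed thresholds", {
  p <- peat_params()
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 25)
  expect_message(
    sw <- sweep_nutrient_input(c(0.02, 0.05, 0.1, 0.15, 0.2), p, cfg, g,
                               seed = 5),
    "overflow cap") # plant-free runs have no closed water balance
  expect_equal(sw$h_cap, 2)
  expect_true(all(sw$records$regime == 1))
  expect_true(all(sw$records$B_fill < 1e-3))
  expect_true(is.na(sw$thresholds["t12"]))
  expect_true(is.na(sw$thresholds["t34"]))
})

test_that("single-value sensitivity scan reproduces the plain sweep", {
  p <- peat_params()
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 20)
  ladder <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  tab <- sensitivity_scan("p", 0.5, ladder, p, cfg, g, seed = 9)
  expect_equal(nrow(tab), 1)
  sw <- suppressMessages(
    sweep_nutrient_input(ladder, p, cfg, g, seed = derive_seeds(9, 1)[1]))
  expect_equal(unlist(tab[1, -1]), sw$thresholds)
  expect_error(sensitivity_scan("k", 1, ladder, p, cfg, g),
               class = "peat_invalid_parameter")
})

test_that("steady regimes do not regress as nutrient input increases", {
  # monotone (plateau-allowed) regime index along a small stabilized sweep
  p <- peat_params()
  g <- sim_grid(32, 32, 4)
  cfg <- sim_config(dt = 1e-3, duration = 150)
  sw <- suppressMessages(
    sweep_nutrient_input(c(0.1, 1.0, 2.5, 4.0, 5.0), p, cfg, g, seed = 4))
  reg <- sw$records$regime[!is.na(sw$records$regime)]
  expect_true(all(diff(reg) >= 0))
  expect_equal(reg[1], 1) # plant-free at the bottom of the ladder
})

test_that("a constant scenario equal to baseline continues the run unchanged", {
  p <- peat_params(N_in = 1.5)
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 30)
  init <- random_initial_state(g, p, seed = 6)
  spin <- run_simulation(init, p, NULL, cfg, g)
  scen <- constant_climate(10, p$p, start_year = 31)
  a <- apply_climate_scenario(spin$final, scen, p, cfg, g)
  cfg2 <- cfg; cfg2$duration <- 10L; cfg2$snapshot_interval <- 1L
  b <- run_simulation(spin$final, p, NULL, cfg2, g)
  expect_equal(a$final$B, b$final$B, tolerance = 1e-12)
  expect_equal(a$yearly$mean_B, b$yearly$mean_B, tolerance = 1e-12)
  expect_equal(nrow(a$regimes), 10)
})

test_that("vegetated peatlands track precipitation; plant-free ones cannot", {
  p <- peat_params()
  g <- sim_grid(16, 16, 4)
  cfg <- sim_config(dt = 1e-3, duration = 60)
  # vegetated: N_in = 1.5 (regime >= 2) - ET follows precip within ~1-2 yr
  init <- random_initial_state(g, peat_params(N_in = 1.5), seed = 10)
  spin <- run_simulation(init, peat_params(N_in = 1.5), NULL, cfg, g)
  scen <- synthetic_climate(40, mean_precip = 0.5, sd_precip = 0.1,
                            start_year = 61, seed = 13)
  tr <- apply_climate_scenario(spin$final, scen, peat_params(N_in = 1.5),
                               cfg, g)
  cc <- sapply(0:3, function(lag) {
    n <- nrow(tr$yearly)
    stats::cor(tr$yearly$precip[1:(n - lag)],
               tr$yearly$mean_ET[(1 + lag):n])
  })
  expect_gt(max(cc[1:2]), 0.6) # peak correlation at lag 0-1 yr
  # plant-free: no transpiration response, B stays ~0; the open water budget
  # needs the overflow ceiling
  inits <- random_initial_state(g, peat_params(N_in = 0.05), seed = 10)
  spin0 <- suppressMessages(
    run_simulation(inits, peat_params(N_in = 0.05), NULL, cfg, g, h_cap = 2))
  tr0 <- suppressMessages(
    apply_climate_scenario(spin0$final, scen, peat_params(N_in = 0.05),
                           cfg, g, h_cap = 2))
  expect_lt(max(tr0$yearly$mean_B), 1)
  # evapotranspiration capped by evaporation alone (f <= 1): cannot balance
  # high precipitation
  expect_lt(max(tr0$yearly$mean_ET), 0.31)
})

test_that("pattern persists through climate fluctuations outside droughts", {
  p <- peat_params(N_in = 2.5)
  g <- sim_grid(32, 32, 4)
  cfg <- sim_config(dt = 1e-3, duration = 150)
  init <- random_initial_state(g, p, seed = 14)
  spin <- run_simulation(init, p, NULL, cfg, g)
  before <- pattern_summary(spin$final, g)
  scen <- synthetic_climate(25, mean_precip = 0.5, sd_precip = 0.05,
                            start_year = 151, seed = 15)
  tr <- apply_climate_scenario(spin$final, scen, p, cfg, g)
  # regime and cluster counts stay put through the fluctuating years
  expect_true(all(tr$regimes$regime == before$regime))
  expect_true(all(abs(tr$regimes$B_count - before$B_count) <=
                    pmax(1, 0.2 * before$B_count)))
})
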