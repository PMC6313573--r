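test_that("gaussian field simulation honors degenerate variograms", {
  cfg <- scenario_config(grid_nx = 20, grid_ny = 20, cell_size_km = 1)
  # zero variance -> constant field
  f0 <- simulate_gaussian_field(cfg, variogram_model("spherical", 0, 0, 10), 1)
  expect_true(all(f0$values == f0$values[1, 1]))
  # invalid parameters rejected
  expect_error(variogram_model("spherical", -1, 1, 10))
  expect_error(variogram_model("spherical", 0, 1, 0))
})

test_that("pure-nugget field behaves as white noise", {
  cfg <- scenario_config(grid_nx = 200, grid_ny = 200, cell_size_km = 1)
  f <- simulate_gaussian_field(cfg, variogram_model("spherical", 1, 0, 10), 7)
  v <- f$values
  g1 <- mean((v[, -1] - v[, -ncol(v)])^2) / 2   # lag-1 semivariance
  expect_lt(abs(g1 - 1), 0.1)
  expect_lt(abs(stats::var(as.vector(v)) - 1), 0.1)
})

test_that("field simulation is deterministic under a fixed seed", {
  cfg <- scenario_config(grid_nx = 30, grid_ny = 25, cell_size_km = 2)
  vg <- variogram_model("exponential", 0.1, 0.9, 12)
  expect_identical(simulate_gaussian_field(cfg, vg, 11)$values,
                   simulate_gaussian_field(cfg, vg, 11)$values)
  co <- data.frame(x_km = runif(50, 0, 50), y_km = runif(50, 0, 50))
  expect_identical(simulate_gaussian_points(co, vg, 3),
                   simulate_gaussian_points(co, vg, 3))
})

test_that("simulated grid fields reproduce the target covariance", {
  cfg <- scenario_config(grid_nx = 100, grid_ny = 100, cell_size_km = 1)
  vg <- variogram_model("exponential", 0, 1, 15)
  v <- replicate(5, {
    f <- simulate_gaussian_field(cfg, vg, sample.int(1e6, 1))
    stats::var(as.vector(f$values))
  })
  expect_lt(abs(mean(v) - 1), 0.15)
})

test_that("water panel hits the censoring target and latent correlation", {
  cfg <- scenario_config(n_units = 200, n_substances = 2,
                         substance_correlation = 0.9,
                         censoring_target = 0.88)
  w <- simulate_water_panel(cfg, seed = 3)
  expect_gt(nrow(w$panel), 2000)
  # realized censoring within 3 points of target
  expect_lt(abs(mean(w$panel$censored) - 0.88), 0.03)
  # latent log correlation within 0.05 of request
  lat <- as.data.frame(w$latent)
  wide <- reshape(lat[, c("obs_id", "substance", "value")], idvar = "obs_id",
                  timevar = "substance", direction = "wide")
  r <- cor(log(wide$value.S1), log(wide$value.S2))
  expect_lt(abs(r - 0.9), 0.05)
  # censored records store the DL
  expect_true(all(w$panel$value[w$panel$censored] == w$panel$dl[w$panel$censored]))
})

test_that("water panel honors zero censoring and determinism", {
  cfg <- scenario_config(n_units = 40, censoring_target = 0)
  w <- simulate_water_panel(cfg, seed = 5)
  expect_equal(sum(w$panel$censored), 0)
  w2 <- simulate_water_panel(cfg, seed = 5)
  expect_identical(w$panel$value, w2$panel$value)
  expect_identical(w$network, w2$network)
  # infeasible correlation rejected
  expect_error(scenario_config(n_substances = 2, substance_correlation = -2),
               "correlation")
})

test_that("network links units to municipalities with populations", {
  cfg <- scenario_config(n_units = 50, n_municipalities = 30,
                         censoring_target = 0)
  w <- simulate_water_panel(cfg, seed = 8)
  expect_true(all(w$network$served_population >= 0))
  expect_true(all(w$network$unit_id %in% seq_len(50)))
  # a unit serving one municipality gets full weight there after aggregation
  um <- data.frame(unit_id = w$network$unit_id[1], mean = 4, sd = 0, n_obs = 1)
  net1 <- w$network[1, ]
  mc <- municipality_concentration(um, net1)
  expect_equal(mc$value, 4)
})

test_that("soil survey censors at the requested rate and reflects sources", {
  cfg <- scenario_config(grid_nx = 50, grid_ny = 50, cell_size_km = 3,
                         n_polluted_sites = 25, soil_spacing_km = 6,
                         soil_censoring_target = 0.68)
  soi <- simulate_soil_survey(cfg, seed = 2)
  expect_lt(abs(mean(soi$obs$censored) - 0.68), 0.05)
  # latent field is hotter near polluted sites than far away
  co <- raster_coords(soi$truth)
  D <- apply(cbind(co$x_km, co$y_km), 1, function(p)
    min(sqrt((p[1] - soi$sites$x_km)^2 + (p[2] - soi$sites$y_km)^2)))
  lt <- log(as.vector(soi$truth$values))
  expect_gt(mean(lt[D <= 3]), mean(lt[D > 10]))
  # no sites -> field independent of source structure
  cfg0 <- scenario_config(grid_nx = 30, grid_ny = 30, n_polluted_sites = 0)
  soi0 <- simulate_soil_survey(cfg0, seed = 2)
  expect_equal(nrow(soi0$sites), 0)
  # censoring off -> zero censored
  soiU <- simulate_soil_survey(cfg0, seed = 2, censor = FALSE)
  expect_equal(sum(soiU$obs$censored), 0)
})

test_that("air year responds to year_effect and emissions as designed", {
  cfg <- scenario_config(grid_nx = 40, grid_ny = 40, n_stations = 76)
  a0 <- simulate_air_year(cfg, year_effect = 0, seed = 23)
  ic <- cells_of(a0$obs, cfg)
  r0 <- cor(a0$altitude$values[ic], a0$obs$value)
  expect_lt(abs(r0), 0.2)
  # doubling emissions raises every station mean (proxy coefficient > 0)
  a2 <- simulate_air_year(cfg, year_effect = 0, seed = 23,
                          beta = c(intercept = 1.2, proxy = 0.04,
                                   altitude = -1e-3, population = 5e-4))
  expect_true(all(a2$obs$value >= a0$obs$value - 1e-12))
  # determinism
  b <- simulate_air_year(cfg, year_effect = 1, seed = 9)
  b2 <- simulate_air_year(cfg, year_effect = 1, seed = 9)
  expect_identical(b$obs$value, b2$obs$value)
  expect_error(simulate_air_year(scenario_config(n_stations = 5), 1, 1),
               "stations")
})

test_that("receptor profiles partition the lifetime and round-trip", {
  rec <- make_receptors()
  expect_named(rec, c("child_0_17", "adult_17_70"))
  expect_equal(rec$child_0_17$exposure_duration +
                 rec$adult_17_70$exposure_duration, 70)
  expect_true(all(vapply(rec, function(r) r$body_weight > 0, logical(1))))
  f <- tempfile(fileext = ".yaml")
  write_receptors(rec, f)
  rec2 <- read_receptors(f)
  expect_equal(rec2, rec, ignore_attr = TRUE)
  # self-consumption 0 zeroes the homegrown pathway downstream
  r0 <- receptor_profile("adult_17_70", 70, 2, 20, 16,
                         c(leaf = 90, root = 120, fruit = 150), 0, 53)
  d <- compute_ladd(list(air = 1, soil = 1, water = 0.001,
                         veg = veg_transfer(1, 1),
                         commercial = c(leaf = 2e-3, root = 2e-3,
                                        fruit = 2e-3)), r0)
  expect_equal(d$ladd$homegrown_veg, 0)
})
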