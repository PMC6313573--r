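test_that("vegetable transfer is linear in air and soil", {
  tp <- default_transfer_params()
  z <- veg_transfer(0, 0, tp)
  expect_true(all(z == 0))
  v1 <- veg_transfer(2, 1, tp)
  # doubling soil doubles the root term only
  v2 <- veg_transfer(2, 2, tp)
  root1 <- veg_transfer(0, 1, tp)
  expect_equal(v2 - v1, root1, tolerance = 1e-12)
  # unit hand-check: 1 mg/kg soil with a 0.01 soil-to-plant factor
  tp$soil_to_plant <- c(leaf = 0.01, root = 0.01, fruit = 0.01)
  expect_equal(unname(veg_transfer(0, 1, tp)[1, ]), rep(0.01, 3))
  tp$yield_kg_m2 <- c(leaf = 0, root = 1, fruit = 1)
  expect_error(veg_transfer(1, 1, tp), "yields")
})

test_that("water LADD matches the hand-computed reference case", {
  r <- receptor_profile("adult_17_70", body_weight = 70, water_intake = 2,
                        soil_ingestion = 0, inhalation_rate = 0,
                        veg_intake = c(leaf = 0, root = 0, fruit = 0),
                        self_consumption = 0, exposure_duration = 53)
  media <- list(air = 0, soil = 0, water = 0.001,
                veg = veg_transfer(0, 0),
                commercial = c(leaf = 0, root = 0, fruit = 0))
  d <- compute_ladd(media, r)
  expect_equal(d$ladd$water, 0.001 * 2 * 53 / (70 * 70),
               tolerance = 1e-10)
  expect_equal(d$ladd$water, 2.163e-5, tolerance = 1e-3)
})

test_that("LADDs are linear, homogeneous, and pathway-independent", {
  rec <- make_receptors()$adult_17_70
  base <- list(air = 1.5, soil = 0.4, water = 2e-6,
               veg = veg_transfer(1.5, 0.4),
               commercial = c(leaf = 2e-3, root = 2e-3, fruit = 2e-3))
  d0 <- compute_ladd(base, rec)
  expect_true(all(unlist(d0$ladd) >= 0))
  # zero media -> zero doses
  zero <- list(air = 0, soil = 0, water = 0, veg = veg_transfer(0, 0),
               commercial = c(leaf = 0, root = 0, fruit = 0))
  expect_true(all(unlist(compute_ladd(zero, rec)$ladd) == 0))
  # doubling water doubles the water LADD and nothing else
  w2 <- base; w2$water <- base$water * 2
  d2 <- compute_ladd(w2, rec)
  expect_equal(d2$ladd$water, 2 * d0$ladd$water)
  for (p in c("soil", "air_inhalation", "homegrown_veg", "commercial_food"))
    expect_equal(d2$ladd[[p]], d0$ladd[[p]])
  expect_error(compute_ladd(within(base, water <- -1), rec), "negative")
})

test_that("EIR aggregates routes linearly and contributions sum to one", {
  rec <- make_receptors()$child_0_17
  media <- list(air = 1, soil = 0.3, water = 2e-6,
                veg = veg_transfer(1, 0.3),
                commercial = c(leaf = 2e-3, root = 2e-3, fruit = 2e-3))
  d <- compute_eir(compute_ladd(media, rec))
  expect_equal(d$eir$total, d$eir$ingestion + d$eir$inhalation)
  expect_equal(sum(unlist(d$contributions)), 1, tolerance = 1e-12)
  # slope factor 1 on a 1e-6 dose gives risk 1e-6 (prints as 1 at x10^6)
  r1 <- receptor_profile("adult_17_70", 70, 1, 0, 0,
                         c(leaf = 0, root = 0, fruit = 0), 0, 70)
  m1 <- list(air = 0, soil = 0, water = 7e-5, veg = veg_transfer(0, 0),
             commercial = c(leaf = 0, root = 0, fruit = 0))
  dd <- compute_ladd(m1, r1)              # water LADD = 1e-6
  expect_equal(dd$ladd$water, 1e-6)
  ee <- compute_eir(dd, c(ingestion = 1, inhalation = 1))
  expect_equal(ee$eir$total, 1e-6)
  # zero doses -> zero risk
  z <- compute_eir(compute_ladd(list(air = 0, soil = 0, water = 0,
                                     veg = veg_transfer(0, 0),
                                     commercial = c(leaf = 0, root = 0,
                                                    fruit = 0)), rec))
  expect_equal(z$eir$total, 0)
  expect_error(compute_eir(d, c(ingestion = 0, inhalation = 1)), "slope")
})

test_that("exposure maps propagate masks and keep uniform media uniform", {
  mkr <- function(v, mm = NULL, mi = NULL)
    raster_field(matrix(v, 4, 4), 3,
                 mask_missing = mm %||% matrix(FALSE, 4, 4),
                 mask_invalid = mi %||% matrix(FALSE, 4, 4))
  mm <- matrix(FALSE, 4, 4); mm[1, 1] <- TRUE
  mi <- matrix(FALSE, 4, 4); mi[4, 4] <- TRUE
  water <- mkr(2e-6, mm = mm)
  soil <- mkr(0.3)
  air <- mkr(1, mi = mi)
  ex <- map_exposure(water, soil, air, make_receptors())
  tot <- ex$adult_17_70$eir$total
  expect_true(tot$mask_missing[1, 1])
  expect_true(tot$mask_invalid[4, 4])
  ok <- !(tot$mask_missing | tot$mask_invalid)
  expect_lt(diff(range(tot$values[ok])), 1e-18)
  expect_true(all(tot$values[ok] > 0))
  # contribution table sums to one
  expect_equal(sum(ex$child_0_17$contributions$mean_share), 1,
               tolerance = 1e-9)
})

test_that("spatial variance of ingestion risk comes from the varying pathways only", {
  set.seed(8)
  mkr <- function(v) raster_field(matrix(v, 5, 5), 3)
  water <- mkr(runif(25, 1e-6, 4e-6))
  soil <- mkr(runif(25, 0.1, 0.6))
  air <- mkr(runif(25, 0.5, 2))
  ex <- map_exposure(water, soil, air, make_receptors())
  e <- ex$adult_17_70
  ing <- e$eir$ingestion$values
  varying <- e$ladd$water$values + e$ladd$soil$values +
    e$ladd$homegrown_veg$values
  expect_equal(stats::var(as.vector(ing)),
               stats::var(as.vector(varying * 7.3)), tolerance = 1e-10)
})
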