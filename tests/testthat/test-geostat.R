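test_that("empirical variogram implements the Matheron estimator", {
  # constant field -> zero semivariance everywhere
  set.seed(1)
  obs <- observation_set(runif(30, 0, 10), runif(30, 0, 10), rep(5, 30))
  emp <- empirical_variogram(obs, seq(0, 10, by = 2))
  expect_true(all(emp$gamma == 0))
  # two points one unit apart with values 0 and 2 -> gamma = 2
  o2 <- observation_set(c(0, 1), c(0, 0), c(0, 2))
  e2 <- empirical_variogram(o2, c(0.5, 1.5))
  expect_equal(e2$gamma, 2)
  expect_equal(e2$n_pairs, 1L)
  expect_error(empirical_variogram(observation_set(1, 1, 1), c(0, 1)))
})

test_that("white-noise semivariance is flat at the marginal variance", {
  set.seed(2)
  n <- 2000
  obs <- observation_set(runif(n, 0, 100), runif(n, 0, 100), rnorm(n, 0, 2))
  emp <- empirical_variogram(obs, seq(0, 50, by = 10))
  expect_true(all(abs(emp$gamma - 4) / 4 < 0.1))
})

test_that("variogram fit recovers exact model evaluations", {
  true <- variogram_model("spherical", 0.1, 0.9, 20)
  lag <- c(1, 2, 4, 6, 9, 12, 16, 20, 25, 30)
  emp <- data.frame(lag = lag, gamma = vgm_gamma(true, lag), n_pairs = 100)
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-3)
  expect_equal(fit$psill, 0.9, tolerance = 1e-3)
  expect_equal(fit$range_km, 20, tolerance = 1e-3)
  # flat empirical variogram -> pure-nugget behavior at every observed lag
  flat <- data.frame(lag = lag, gamma = 0.7, n_pairs = 50)
  ff <- fit_variogram(flat, "spherical")
  expect_equal(unname(vgm_gamma(ff, lag)), rep(0.7, length(lag)),
               tolerance = 1e-3)
  expect_equal(ff$nugget + ff$psill, 0.7, tolerance = 0.02)
  expect_error(fit_variogram(emp[1:2, ], "spherical"), "bins")
})

test_that("ordinary kriging is exact, unbiased and matches the hand-solved system", {
  vm <- variogram_model("spherical", 0, 1, 4)
  obs <- observation_set(c(0, 3, 0), c(0, 0, 2), c(1, 2, 3))
  # exactness at a datum with zero nugget
  at <- ordinary_krige(obs, vm, data.frame(x_km = 0, y_km = 2))
  expect_equal(at$pred, 3, tolerance = 1e-10)
  expect_equal(at$krig_var, 0, tolerance = 1e-10)
  # single observation -> constant surface
  one <- observation_set(5, 5, 7)
  k1 <- ordinary_krige(one, vm, data.frame(x_km = c(0, 9), y_km = c(0, 1)))
  expect_equal(k1$pred, c(7, 7))
  # hand-assembled 4x4 kriging system as the oracle
  target <- c(1, 1)
  co <- cbind(obs$x_km, obs$y_km)
  D <- as.matrix(dist(co))
  C <- vgm_cov(vm, D)
  A <- rbind(cbind(C, 1), c(1, 1, 1, 0))
  d0 <- sqrt(rowSums((co - matrix(target, 3, 2, byrow = TRUE))^2))
  b <- c(vgm_cov(vm, d0), 1)
  lam <- solve(A, b)
  pred_hand <- sum(lam[1:3] * obs$value)
  var_hand <- vgm_cov(vm, 0) - sum(lam[1:3] * b[1:3]) - lam[4]
  k <- ordinary_krige(obs, vm, data.frame(x_km = target[1], y_km = target[2]))
  expect_equal(k$pred, pred_hand, tolerance = 1e-8)
  expect_equal(k$krig_var, max(var_hand, 0), tolerance = 1e-8)
})

test_that("kriging weights sum to one (affine equivariance)", {
  vm <- variogram_model("exponential", 0.2, 0.8, 10)
  set.seed(3)
  obs <- observation_set(runif(12, 0, 30), runif(12, 0, 30), rnorm(12))
  tg <- data.frame(x_km = runif(6, 0, 30), y_km = runif(6, 0, 30))
  k1 <- ordinary_krige(obs, vm, tg)
  obs2 <- obs; obs2$value <- obs$value + 5
  k2 <- ordinary_krige(obs2, vm, tg)
  expect_equal(k2$pred, k1$pred + 5, tolerance = 1e-8)
  expect_true(all(k1$krig_var >= 0))
})

test_that("indicator kriging equals ordinary kriging on the 0/1 indicators", {
  set.seed(4)
  obs <- observation_set(runif(10, 0, 20), runif(10, 0, 20),
                         runif(10), censored = rep(c(TRUE, FALSE), 5))
  tg <- data.frame(x_km = runif(15, 0, 20), y_km = runif(15, 0, 20))
  vm <- variogram_model("spherical", 0.05, 0.2, 8)
  ik <- indicator_krige(obs, tg, model = vm, clip = FALSE)
  iobs <- obs; iobs$value <- as.numeric(!obs$censored)
  ok <- ordinary_krige(iobs, vm, tg)
  expect_equal(ik$prob, ok$pred, tolerance = 1e-12)
  ikc <- indicator_krige(obs, tg, model = vm)
  expect_true(all(ikc$prob >= 0 & ikc$prob <= 1))
  # single-class input collapses to a constant surface with a warning
  allup <- obs; allup$censored <- FALSE
  expect_warning(ik1 <- indicator_krige(allup, tg), "single-class")
  expect_true(all(ik1$prob == 1))
  alldn <- obs; alldn$censored <- TRUE
  expect_warning(ik0 <- indicator_krige(alldn, tg), "single-class")
  expect_true(all(ik0$prob == 0))
})

test_that("residual kriging reduces to ordinary kriging for a constant trend", {
  set.seed(5)
  obs <- observation_set(runif(20, 0, 40), runif(20, 0, 40), rnorm(20, 10))
  tg <- data.frame(x_km = runif(8, 0, 40), y_km = runif(8, 0, 40))
  X <- data.frame(c0 = rep(1, 20))
  Xt <- data.frame(c0 = rep(1, 8))
  rk <- residual_krige(obs, X, Xt, tg, trend = "linear")
  robs <- obs; robs$value <- obs$value - mean(obs$value)
  ok <- ordinary_krige(robs, rk$resid_model, tg)
  expect_equal(rk$pred, mean(obs$value) + ok$pred, tolerance = 1e-8)
})

test_that("residual kriging on a noiseless linear field is exact", {
  set.seed(6)
  x <- runif(40, 0, 30); y <- runif(40, 0, 30)
  obs <- observation_set(x, y, 2 * x)
  X <- data.frame(x = x)
  tg <- data.frame(x_km = runif(10, 0, 30), y_km = runif(10, 0, 30))
  Xt <- data.frame(x = tg$x_km)
  rk <- residual_krige(obs, X, Xt, tg, trend = "linear")
  expect_equal(rk$pred, 2 * tg$x_km, tolerance = 1e-6)
  cv <- loocv_residual_krige(obs, X, trend = "linear")
  expect_lt(cv$rmse, 1e-6)
})

test_that("leave-one-out cross-validation scores ME and RMSE correctly", {
  obs <- observation_set(c(0, 1, 2, 3), c(0, 0, 0, 0), c(1, 2, 3, 4))
  # perfect predictor
  cv0 <- loocv(obs, function(tr, te) te$value)
  expect_equal(cv0$me, 0); expect_equal(cv0$rmse, 0)
  # constant offsets: errors {+1,+1,+1,+1} -> ME 1, RMSE 1
  cv1 <- loocv(obs, function(tr, te) te$value + 1)
  expect_equal(cv1$me, 1); expect_equal(cv1$rmse, 1)
  # alternating errors {+2,-2,...} -> ME 0, RMSE 2
  k <- 0
  cv2 <- loocv(obs, function(tr, te) te$value + c(2, -2, 2, -2)[which(
    obs$x_km == te$x_km)])
  expect_equal(cv2$me, 0); expect_equal(cv2$rmse, 2)
  # failing folds are skipped and counted
  cv3 <- loocv(obs, function(tr, te) if (te$x_km == 0) stop("boom") else te$value)
  expect_equal(cv3$n_failed, 1)
  expect_error(loocv(obs[1:2, ], function(tr, te) 0), ">= 3")
  # stratified report by station type
  obs$type <- c("a", "a", "b", "b")
  cvt <- loocv(obs, function(tr, te) te$value + 1)
  expect_equal(sort(cvt$by_type$type), c("a", "b"))
  expect_equal(cvt$by_type$me, c(1, 1))
})

test_that("duplicate coordinates are averaged with a warning", {
  expect_warning(o <- observation_set(c(1, 1, 2), c(1, 1, 2), c(2, 4, 9)),
                 "duplicated")
  expect_equal(nrow(o), 2)
  expect_equal(o$value[o$x_km == 1], 3)
})
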