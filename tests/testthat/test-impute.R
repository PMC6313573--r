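test_that("censored_panel validates its records", {
  expect_error(censored_panel(data.frame(unit_id = 1)), "columns")
  # censored record must store the DL
  bad <- data.frame(obs_id = 1, unit_id = 1, date = as.Date("2005-01-01"),
                    substance = "S1", value = 0.2, censored = TRUE, dl = 1)
  expect_error(censored_panel(bad), "DL")
  bad$dl <- 0
  expect_error(censored_panel(bad), "detection limits")
})

test_that("substitution rules replace censored values by their own DL rule", {
  p <- make_tiny_panel(c(5, 6, 7), c(5, 6, 7), dl = 1)
  cen <- artificial_censor(p, threshold = 6)
  expect_equal(substitute_censored(cen, "half_dl")$value[cen$censored],
               rep(3, sum(cen$censored)))
  expect_equal(substitute_censored(cen, "dl_over_sqrt2")$value[cen$censored],
               rep(6 / sqrt(2), sum(cen$censored)))
  expect_equal(substitute_censored(cen, "zero")$value[cen$censored],
               rep(0, sum(cen$censored)))
  expect_error(substitute_censored(cen, "nope"))
  # DL/sqrt(2) at DL = 3 is about 2.1213
  p3 <- make_tiny_panel(c(1, 4), c(1, 4))
  c3 <- artificial_censor(p3, 3)
  expect_equal(substitute_censored(c3, "dl_over_sqrt2")$value[c3$censored],
               rep(2.1213203, sum(c3$censored)), tolerance = 1e-6)
})

test_that("artificial censoring flags below-threshold values and edge cases", {
  p <- make_tiny_panel(c(1, 2, 3, 4), c(1, 2, 3, 4))
  cen <- artificial_censor(p, 2.5)
  expect_equal(sum(cen$censored), 4)
  expect_equal(attr(cen, "censoring_rate"), 0.5)
  expect_true(all(cen$value[cen$censored] == 2.5))
  # threshold below min -> nothing censored
  expect_equal(sum(artificial_censor(p, 0.5)$censored), 0)
  # threshold censoring everything -> error
  expect_error(artificial_censor(p, 100), "100%")
})

test_that("imputation bias statistics match hand arithmetic", {
  p <- make_tiny_panel(c(1, 2), c(1, 2))
  cen <- artificial_censor(p, 1.5, substances = "S1")
  est <- substitute_censored(cen, "half_dl")
  # perfect estimate
  perf <- est; perf$value <- p$value
  ev <- evaluate_imputation(p, perf)
  expect_equal(ev$ame, 0); expect_equal(ev$rmse, 0)
  # errors {+1, -1} -> AME 1, RMSE 1; errors {0, 2} -> AME 1, RMSE sqrt(2)
  p2 <- make_tiny_panel(c(1, 2, 10), c(1, 2, 10))
  c2 <- artificial_censor(p2, 5, substances = "S1")   # censors values 1 and 2
  e2 <- substitute_censored(c2, "zero")
  e2$value[e2$imputed] <- c(1 + 1, 2 - 1)
  ev2 <- evaluate_imputation(p2, e2)
  expect_equal(ev2$ame, 1); expect_equal(ev2$rmse, 1)
  e3 <- substitute_censored(c2, "zero")
  e3$value[e3$imputed] <- c(1 + 0, 2 + 2)
  ev3 <- evaluate_imputation(p2, e3)
  expect_equal(ev3$ame, 1); expect_equal(ev3$rmse, sqrt(2))
  # no censored cells -> error
  expect_error(evaluate_imputation(p, substitute_censored(
    artificial_censor(p, 0.5), "zero")), "no censored")
})

test_that("bootstrap EM returns m complete panels with invariants intact", {
  cfg <- scenario_config(n_units = 60, censoring_target = 0.8)
  w <- simulate_water_panel(cfg, seed = 13)
  imp <- em_bootstrap_impute(w$panel, m = 8, seed = 4)
  expect_s3_class(imp, "imputed_panel_set")
  expect_length(imp$panels, 8)
  cen <- w$panel$censored
  for (pl in imp$panels) {
    expect_false(any(pl$censored))
    # imputed values in (0, DL]
    expect_true(all(pl$value[cen] > 0 & pl$value[cen] <= pl$dl[cen] + 1e-12))
    # uncensored cells bit-identical to the input
    expect_identical(pl$value[!cen], w$panel$value[!cen])
  }
  # across-imputation diagnostics cover every censored cell
  expect_equal(nrow(imp$diagnostics), sum(cen))
  # determinism
  imp2 <- em_bootstrap_impute(w$panel, m = 8, seed = 4)
  expect_identical(imp$panels[[3]]$value, imp2$panels[[3]]$value)
})

test_that("a panel without censoring passes through imputation unchanged", {
  p <- make_tiny_panel(c(1, 2, 3), c(2, 3, 4))
  imp <- em_bootstrap_impute(p, m = 3, seed = 1)
  for (pl in imp$panels) expect_equal(pl$value, p$value)
})

test_that("near-perfect substance correlation pins imputations to the regression prediction", {
  # S2 = 2 * S1 on the log scale up to epsilon; one censored S1 cell whose
  # partner is observed puts the imputation at the conditional prediction
  set.seed(42)
  n <- 60
  l1 <- rnorm(n, 0, 1)
  l2 <- 0.5 * l1 + rnorm(n, 0, 0.01)
  v1 <- exp(l1); v2 <- exp(l2)
  p <- make_tiny_panel(v1, v2)
  # censor exactly the smallest S1 value, keep everything else observed
  thr <- sort(v1)[2] * 0.999
  cen <- artificial_censor(p, thr, substances = "S1")
  expect_equal(sum(cen$censored), 1)
  i <- which(cen$censored)
  imp <- em_bootstrap_impute(cen, m = 8, seed = 7)
  pooled <- pool_imputations(imp)
  # conditional prediction of log S1 given log S2 ~ 2 * log S2
  pred <- exp(2 * log(v2[which(v1 == min(v1))]))
  target <- min(pred, thr)
  expect_lt(abs(log(pooled$value[i]) - log(target)), 0.35)
})

test_that("imputation degrades gracefully on degenerate panels", {
  # single substance cannot exploit correlations
  one <- make_tiny_panel(c(1, 2, 3), c(1, 2, 3))
  one <- one[one$substance == "S1", ]
  class(one) <- c("censored_panel", "data.frame")
  cen <- artificial_censor(one, 2.5)
  expect_error(em_bootstrap_impute(cen, m = 3, seed = 1), "substances")
  # m below 2 rejected
  p <- make_tiny_panel(c(1, 5), c(1, 5))
  expect_error(em_bootstrap_impute(artificial_censor(p, 2), m = 1, seed = 1))
})

test_that("pooled AME does not get worse with more imputations", {
  cfg <- scenario_config(n_units = 50, censoring_target = 0)
  ames <- sapply(1:3, function(s) {
    w <- simulate_water_panel(cfg, seed = s)
    wide <- reshape(as.data.frame(w$latent)[, c("obs_id", "substance", "value")],
                    idvar = "obs_id", timevar = "substance", direction = "wide")
    thr <- stats::quantile(wide$value.S1, 0.8)
    cen <- artificial_censor(w$latent, thr, substances = "S1")
    c(m2 = evaluate_imputation(w$latent,
                               em_bootstrap_impute(cen, m = 2, seed = s))$ame,
      m8 = evaluate_imputation(w$latent,
                               em_bootstrap_impute(cen, m = 8, seed = s))$ame)
  })
  expect_lte(mean(ames["m8", ]), mean(ames["m2", ]) * 1.05)
})
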