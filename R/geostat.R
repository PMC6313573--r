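#' Variogram model
#'
#' Parametric semivariogram gamma(h) with the three standard parameters:
#' nugget, partial sill and range. Two families are supported: spherical,
#' gamma(h) = nugget + psill * (1.5 h/a - 0.5 (h/a)^3) for h < a and
#' nugget + psill beyond the range a; and exponential,
#' gamma(h) = nugget + psill * (1 - exp(-3 h / a)), where the range a is the
#' practical range (95 percent of the sill).
#'
#' @param family `"spherical"` or `"exponential"`.
#' @param nugget nugget variance (>= 0).
#' @param psill partial sill (>= 0).
#' @param range_km range parameter in km (> 0).
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential"),
                            nugget, psill, range_km) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0) stop("nugget and partial sill must be >= 0")
  if (range_km <= 0) stop("range must be > 0")
  structure(list(family = family, nugget = nugget, psill = psill,
                 range_km = range_km),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model %s: nugget=%.4g psill=%.4g range=%.4g km>\n",
              x$family, x$nugget, x$psill, x$range_km))
  invisible(x)
}

#' Evaluate a variogram model
#'
#' @param model a `variogram_model`
#' @param h nonnegative distances (km)
#' @return gamma(h); gamma(0) = 0 by convention.
#' @export
vgm_gamma <- function(model, h) {
  g <- switch(model$family,
    spherical = {
      r <- pmin(h / model$range_km, 1)
      model$psill * (1.5 * r - 0.5 * r^3)
    },
    exponential = model$psill * (1 - exp(-3 * h / model$range_km))
  )
  out <- model$nugget + g
  out[h == 0] <- 0
  out
}

#' Stationary covariance implied by a variogram model
#'
#' C(h) = sill - gamma(h), with C(0) = nugget + psill (total sill).
#' @inheritParams vgm_gamma
#' @export
vgm_cov <- function(model, h) {
  model$nugget + model$psill - vgm_gamma(model, h)
}

dist_xy <- function(a, b = NULL) {
  # pairwise euclidean distances between rows of 2-col matrices (km)
  if (is.null(b)) b <- a
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Georeferenced point observations
#'
#' Construct an observation set: point measurements with coordinates in km,
#' optional censoring flags and detection limits, and an optional metadata
#' class (e.g. station type) used to stratify cross-validation reports.
#' Duplicated coordinates are averaged with a warning, as a kriging system
#' requires unique support points.
#'
#' @param x_km,y_km coordinates (km)
#' @param value measured values
#' @param censored logical; `TRUE` where the value is below the detection limit
#' @param dl detection limit per observation
#' @param type optional character metadata class
#' @return data.frame of class `observation_set`
#' @export
observation_set <- function(x_km, y_km, value, censored = FALSE, dl = NA_real_,
                            type = NA_character_) {
  d <- data.frame(x_km = x_km, y_km = y_km, value = value,
                  censored = censored, dl = dl, type = type,
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$value))) stop("non-finite observation values")
  key <- paste(d$x_km, d$y_km)
  if (anyDuplicated(key)) {
    warning("duplicated coordinates averaged")
    d <- do.call(rbind, lapply(split(d, key), function(g) {
      g$value[1] <- mean(g$value); g$censored[1] <- any(g$censored); g[1, ]
    }))
    rownames(d) <- NULL
  }
  class(d) <- c("observation_set", "data.frame")
  d
}

#' Empirical (Matheron) semivariogram
#'
#' gamma_hat(h) = 1/(2 N_h) * sum over pairs in the bin of (z_i - z_j)^2,
#' with half-open lag bins [a, b). Bins with zero pairs are omitted.
#'
#' @param obs an `observation_set` (or data.frame with x_km, y_km, value)
#' @param lag_edges increasing vector of bin edges (km)
#' @return data.frame with `lag` (bin midpoint), `gamma`, `n_pairs`
#' @export
empirical_variogram <- function(obs, lag_edges) {
  if (nrow(obs) < 2) stop("need at least two points")
  if (is.unsorted(lag_edges, strictly = TRUE)) stop("lag_edges must increase")
  co <- cbind(obs$x_km, obs$y_km)
  D <- dist_xy(co)
  iu <- upper.tri(D)
  h <- D[iu]
  if (all(h == 0)) stop("all points coincident")
  dz2 <- (outer(obs$value, obs$value, "-")^2)[iu]
  bin <- findInterval(h, lag_edges, rightmost.closed = FALSE)
  keep <- bin >= 1 & bin < length(lag_edges)
  bin <- bin[keep]; dz2 <- dz2[keep]
  npair <- tabulate(bin, nbins = length(lag_edges) - 1)
  ssq <- vapply(seq_len(length(lag_edges) - 1),
                function(b) sum(dz2[bin == b]), numeric(1))
  mid <- (lag_edges[-1] + lag_edges[-length(lag_edges)]) / 2
  ok <- npair > 0
  data.frame(lag = mid[ok], gamma = ssq[ok] / (2 * npair[ok]),
             n_pairs = npair[ok])
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares with pair-count weights over (nugget, partial sill,
#' range), bounded below at zero (range at a small positive value). Initial
#' values come from the empirical points (first-bin semivariance for the
#' nugget, the plateau for the sill, the lag where the curve reaches ~95% of
#' the plateau for the range); if the optimizer fails, the method-of-moments
#' initial values are returned with a warning.
#'
#' @param emp data.frame from [empirical_variogram()]
#' @param family model family
#' @return a `variogram_model`
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  if (nrow(emp) < 3) stop("need >= 3 nonempty lag bins")
  sill0 <- mean(emp$gamma[emp$lag >= stats::quantile(emp$lag, 0.6)])
  if (!is.finite(sill0) || sill0 <= 0) sill0 <- max(mean(emp$gamma), 1e-8)
  nug0 <- max(min(emp$gamma[which.min(emp$lag)], sill0 * 0.9), 0)
  past <- emp$lag[emp$gamma >= 0.95 * sill0]
  rng0 <- if (length(past)) max(min(past), min(emp$lag)) else max(emp$lag) / 2
  init <- c(nug0, max(sill0 - nug0, 1e-8), rng0)
  obj <- function(p) {
    m <- variogram_model(family, p[1], p[2], p[3])
    sum(emp$n_pairs * (vgm_gamma(m, emp$lag) - emp$gamma)^2)
  }
  fit <- try(stats::optim(init, obj, method = "L-BFGS-B",
                          lower = c(0, 0, max(min(emp$lag) * 0.1, 1e-6)),
                          upper = c(Inf, Inf, max(emp$lag) * 10)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence > 1) {
    warning("variogram WLS did not converge; returning initial values")
    return(variogram_model(family, init[1], init[2], init[3]))
  }
  variogram_model(family, fit$par[1], fit$par[2], fit$par[3])
}

#' Ordinary kriging
#'
#' Global-neighborhood ordinary kriging: the best linear unbiased predictor
#' with weights constrained to sum to one, solved from the full covariance
#' system with a Lagrange multiplier. Exact interpolator at data points;
#' kriging variance is clipped at zero against round-off.
#'
#' @param obs an `observation_set`
#' @param model a `variogram_model`
#' @param targets matrix or data.frame with columns x_km, y_km
#' @return data.frame with `pred` and `krig_var` per target
#' @export
ordinary_krige <- function(obs, model, targets) {
  targets <- as.matrix(as.data.frame(targets)[, c("x_km", "y_km")])
  n <- nrow(obs)
  if (n < 1) stop("need at least one observation")
  co <- cbind(obs$x_km, obs$y_km)
  if (n == 1) {
    return(data.frame(pred = rep(obs$value, nrow(targets)),
                      krig_var = vgm_gamma(model, dist_xy(targets, co)[, 1]) * 2))
  }
  sill <- model$nugget + model$psill
  C <- vgm_cov(model, dist_xy(co))
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  c0 <- vgm_cov(model, dist_xy(co, targets))          # n x m
  B <- rbind(c0, 1)
  lam <- try(solve(A, B), silent = TRUE)
  if (inherits(lam, "try-error")) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8 * sill
    lam <- try(solve(A, B), silent = TRUE)
    if (inherits(lam, "try-error")) stop("singular kriging system")
  }
  w <- lam[seq_len(n), , drop = FALSE]
  mu <- lam[n + 1, ]
  pred <- drop(crossprod(w, obs$value))
  kv <- sill - colSums(w * c0) - mu
  data.frame(pred = pred, krig_var = pmax(kv, 0))
}

#' Indicator kriging of detection-limit exceedance
#'
#' Transforms each observation to the indicator 1{value above the detection
#' limit} (i.e. not censored), ordinary-kriges the indicators, and clips the
#' interpolated values to [0, 1]: the result is the probability of exceeding
#' the detection limit at each target. If only one class is present the
#' surface is the constant 0 or 1 with a warning.
#'
#' @param obs an `observation_set` with `censored` flags
#' @param targets targets as for [ordinary_krige()]
#' @param model optional `variogram_model` for the indicators; fitted
#'   internally (spherical) when `NULL`.
#' @param clip clip predictions to [0,1] (default TRUE; FALSE exposes the raw
#'   ordinary-kriging output)
#' @return data.frame with `prob` (and `krig_var`)
#' @export
indicator_krige <- function(obs, targets, model = NULL, clip = TRUE) {
  ind <- as.numeric(!obs$censored)
  if (length(unique(ind)) == 1) {
    warning("single-class indicator input; constant surface")
    m <- nrow(as.data.frame(targets))
    return(data.frame(prob = rep(ind[1], m), krig_var = rep(0, m)))
  }
  iobs <- obs
  iobs$value <- ind
  if (is.null(model)) {
    span <- max(dist_xy(cbind(obs$x_km, obs$y_km)))
    emp <- empirical_variogram(iobs, seq(0, span / 2, length.out = 13))
    v <- stats::var(ind)
    model <- if (nrow(emp) >= 3) fit_variogram(emp, "spherical") else
      variogram_model("spherical", v / 2, v / 2, span / 4)
  }
  ok <- ordinary_krige(iobs, model, targets)
  data.frame(prob = if (clip) pmin(pmax(ok$pred, 0), 1) else ok$pred,
             krig_var = ok$krig_var)
}

#' Regression (residual) kriging
#'
#' Fits a trend of the observed values on covariates, kriges the residuals
#' with a variogram fitted on them, and predicts trend + kriged residual at
#' the targets. With a constant trend this reduces to ordinary kriging.
#'
#' @param obs an `observation_set`
#' @param X covariate data.frame at the observations (numeric columns)
#' @param X_target covariates at the targets (same columns)
#' @param targets coordinates of targets (x_km, y_km)
#' @param trend `"linear"` (ordinary least squares) or `"random_forest"`
#'   (ranger, permutation importance, seeded)
#' @param family residual variogram family
#' @param num_trees random-forest size
#' @param seed RNG seed for the forest
#' @param lag_edges optional residual-variogram bin edges
#' @return list with `pred`, `trend`, `resid_pred`, `resid_model`
#'   (`variogram_model`), and the fitted `trend_fit`
#' @export
residual_krige <- function(obs, X, X_target, targets,
                           trend = c("linear", "random_forest"),
                           family = c("spherical", "exponential"),
                           num_trees = 500, seed = 1, lag_edges = NULL) {
  trend <- match.arg(trend)
  family <- match.arg(family)
  X <- as.data.frame(X); X_target <- as.data.frame(X_target)
  fit <- fit_trend(obs$value, X, trend, num_trees, seed)
  mu_obs <- predict_trend(fit, X)
  mu_tar <- predict_trend(fit, X_target)
  res <- obs$value - mu_obs
  robs <- obs
  robs$value <- res
  if (is.null(lag_edges)) {
    span <- max(dist_xy(cbind(obs$x_km, obs$y_km)))
    lag_edges <- seq(0, span / 2, length.out = 13)
  }
  emp <- empirical_variogram(robs, lag_edges)
  vm <- if (nrow(emp) >= 3) fit_variogram(emp, family) else
    variogram_model(family, stats::var(res), 1e-8, max(lag_edges) / 2)
  if (vm$nugget + vm$psill < 1e-12) {
    # residuals numerically constant: prediction is the trend plus that constant
    kp <- data.frame(pred = rep(mean(res), nrow(as.data.frame(targets))),
                     krig_var = 0)
  } else {
    kp <- ordinary_krige(robs, vm, targets)
  }
  list(pred = mu_tar + kp$pred, trend = mu_tar, resid_pred = kp$pred,
       krig_var = kp$krig_var, resid_model = vm, trend_fit = fit)
}

fit_trend <- function(y, X, trend, num_trees = 500, seed = 1) {
  if (ncol(X) == 0 || trend == "linear" && all(vapply(X, function(c)
      stats::var(c) == 0, logical(1)))) {
    return(structure(list(mean = mean(y)), class = "trend_const"))
  }
  if (trend == "linear") {
    d <- cbind(.y = y, X)
    structure(list(fit = stats::lm(.y ~ ., data = d)), class = "trend_lm")
  } else {
    d <- cbind(.y = y, X)
    rf <- ranger::ranger(.y ~ ., data = d, num.trees = num_trees,
                         importance = "permutation", seed = seed,
                         num.threads = 1)
    structure(list(fit = rf), class = "trend_rf")
  }
}

predict_trend <- function(fit, X) {
  switch(class(fit)[1],
    trend_const = rep(fit$mean, nrow(X)),
    trend_lm = unname(stats::predict(fit$fit, newdata = X)),
    trend_rf = stats::predict(fit$fit, data = X, num.threads = 1)$predictions
  )
}

#' Leave-one-out cross-validation
#'
#' Predicts each observation from the remaining n - 1 with a user-supplied
#' predictor closure and reports the mean error ME = mean(pred - obs), the
#' RMSE, and per-point errors; a breakdown by the observation `type` metadata
#' is included when present. Failed folds are skipped and counted.
#'
#' @param obs an `observation_set`
#' @param predictor function(train_obs, target_row) -> predicted value, where
#'   `target_row` is the held-out point as a one-row data.frame (coordinates
#'   and any covariate columns; its `value` must not be used)
#' @return list with `me`, `rmse`, `errors`, `by_type`, `n_failed`
#' @export
loocv <- function(obs, predictor) {
  n <- nrow(obs)
  if (n < 3) stop("need >= 3 observations")
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- obs[-i, , drop = FALSE]
    te <- obs[i, , drop = FALSE]
    p <- try(predictor(tr, te), silent = TRUE)
    if (!inherits(p, "try-error") && is.finite(p)) err[i] <- p - obs$value[i]
  }
  ok <- !is.na(err)
  by_type <- NULL
  if (!all(is.na(obs$type))) {
    by_type <- do.call(rbind, lapply(split(which(ok), obs$type[ok]), function(ix)
      data.frame(me = mean(err[ix]), rmse = sqrt(mean(err[ix]^2)),
                 n = length(ix))))
    by_type$type <- rownames(by_type); rownames(by_type) <- NULL
  }
  list(me = mean(err[ok]), rmse = sqrt(mean(err[ok]^2)),
       errors = err, by_type = by_type, n_failed = sum(!ok))
}
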