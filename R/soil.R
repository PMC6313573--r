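#' Inverse-distance source proxy around polluted sites
#'
#' For each location, the sum over polluted sites within `radius_km` of
#' 1 / max(d, d_min) (km^-1); zero when no site falls inside the buffer.
#' `d_min` floors the singularity at colocation (default half a cell width).
#'
#' @param sites data.frame with x_km, y_km
#' @param locations data.frame with x_km, y_km
#' @param radius_km buffer radius (> 0)
#' @param d_min distance floor in km
#' @return numeric proxy per location (km^-1)
#' @export
build_source_proxy <- function(sites, locations, radius_km, d_min = 1.5) {
  if (radius_km <= 0) stop("radius must be > 0")
  if (nrow(sites) == 0) return(rep(0, nrow(locations)))
  D <- dist_xy(cbind(locations$x_km, locations$y_km),
               cbind(sites$x_km, sites$y_km))
  W <- 1 / pmax(D, d_min)
  W[D > radius_km] <- 0
  rowSums(W)
}

#' Select the source-proxy buffer radius by AIC
#'
#' For each candidate radius, builds the proxy at the observations and fits a
#' Gaussian-likelihood linear regression of the observed concentration on the
#' proxy (plus any extra covariates); returns the radius minimizing AIC, ties
#' going to the smaller radius. Radii whose proxy is degenerate (all zero)
#' are skipped with a warning.
#'
#' @param radii candidate radii (km), >= 2 unless a single candidate is given
#' @param obs an `observation_set`
#' @param sites polluted-site data.frame
#' @param covariates optional extra covariate data.frame at the observations
#' @param log_response regress on log(value) (default TRUE, concentrations
#'   being right-skewed)
#' @return list with `radius_km`, `aic` table
#' @export
select_buffer_radius <- function(radii, obs, sites, covariates = NULL,
                                 log_response = TRUE) {
  radii <- sort(radii)
  if (length(radii) == 1) {
    return(list(radius_km = radii, aic = data.frame(radius_km = radii,
                                                    aic = NA_real_)))
  }
  y <- if (log_response) log(obs$value) else obs$value
  aics <- vapply(radii, function(r) {
    pr <- build_source_proxy(sites, obs, r)
    if (all(pr == 0)) {
      warning("degenerate (all-zero) proxy at radius ", r, " km; skipped")
      return(NA_real_)
    }
    d <- data.frame(.y = y, proxy = pr)
    if (!is.null(covariates)) d <- cbind(d, covariates)
    stats::AIC(stats::lm(.y ~ ., data = d))
  }, numeric(1))
  ok <- which(!is.na(aics))
  if (!length(ok)) stop("no candidate radius yields a usable proxy")
  best <- ok[which.min(aics[ok])]       # which.min takes the first = smallest radius
  list(radius_km = radii[best],
       aic = data.frame(radius_km = radii, aic = aics))
}

#' Backward covariate selection by random-forest OOB error
#'
#' Starting from the full candidate stack, repeatedly drops the covariate
#' with the smallest permutation importance, refits the forest, and returns
#' the subset (of any size >= 1) with the minimum out-of-bag mean squared
#' error. Deterministic under a fixed seed.
#'
#' @param y response at the observations
#' @param X candidate covariate data.frame
#' @param num_trees forest size
#' @param seed RNG seed
#' @return list with `selected` (column names), `oob_path` (data.frame of
#'   subset size and OOB MSE)
#' @export
select_covariates_oob <- function(y, X, num_trees = 500, seed = 1L) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) stop("need >= 1 candidate covariate")
  if (ncol(X) == 1) {
    return(list(selected = names(X),
                oob_path = data.frame(size = 1L, oob_mse = NA_real_)))
  }
  current <- names(X)
  best <- NULL
  path <- NULL
  step <- 0L
  while (length(current) >= 1) {
    d <- cbind(.y = y, X[current])
    rf <- ranger::ranger(.y ~ ., data = d, num.trees = num_trees,
                         importance = "permutation",
                         seed = seed + step, num.threads = 1)
    path <- rbind(path, data.frame(size = length(current),
                                   oob_mse = rf$prediction.error))
    if (is.null(best) || rf$prediction.error < best$oob_mse) {
      best <- list(selected = current, oob_mse = rf$prediction.error)
    }
    if (length(current) == 1) break
    imp <- rf$variable.importance
    current <- setdiff(current, names(which.min(imp)))
    step <- step + 1L
  }
  list(selected = best$selected, oob_path = path)
}

#' Map soil concentrations on the reference grid
#'
#' End-to-end soil pipeline: (1) indicator kriging of the detection-limit
#' exceedance gives an exceedance-probability covariate; (2) the
#' inverse-distance source proxy is built at the AIC-selected buffer radius;
#' (3) OOB backward elimination selects among {probability, proxy, soil
#' covariates}; (4) residual kriging with a random-forest trend and a
#' spherical residual variogram produces the map. Censored observations
#' enter the value model at DL/2 (the censoring information itself enters
#' through the probability covariate). Output is clipped at zero and
#' log-transformed internally (concentrations are right-skewed positive).
#'
#' @param obs `observation_set` with censoring flags and `dl`
#' @param covariates named list of covariate `raster_field`s
#' @param sites polluted-site data.frame
#' @param config `scenario_config` (grid geometry)
#' @param candidate_radii_km buffer radii tested by AIC
#' @param trend `"random_forest"` (default) or `"linear"`
#' @param num_trees forest size
#' @param seed RNG seed
#' @param run_loocv attach a leave-one-out report (refits trend per fold)
#' @return list with `map` (`raster_field`, natural scale), `prob`
#'   (exceedance-probability raster), `radius_km`, `selected`, `loocv`
#' @export
map_soil <- function(obs, covariates, sites, config,
                     candidate_radii_km = c(1, 2, 3, 5, 10),
                     trend = "random_forest", num_trees = 500, seed = 1L,
                     run_loocv = TRUE) {
  co <- raster_coords(config)
  cell_of <- function(pts) {
    col <- pmin(pmax(ceiling(pts$x_km / config$cell_size_km), 1), config$grid_nx)
    row <- pmin(pmax(ceiling(pts$y_km / config$cell_size_km), 1), config$grid_ny)
    cbind(row, col)
  }
  # working value: log concentration, censored at DL/2
  yval <- ifelse(obs$censored, obs$dl / 2, obs$value)
  ylog <- log(yval)

  # (1) exceedance-probability covariate
  prob_obs_tar <- indicator_krige(obs, rbind(obs[, c("x_km", "y_km")],
                                             co[, c("x_km", "y_km")]))
  n <- nrow(obs)
  p_obs <- prob_obs_tar$prob[seq_len(n)]
  p_tar <- prob_obs_tar$prob[-seq_len(n)]

  # (2) AIC buffer selection + proxy; the regression adjusts for a few
  # leading soil covariates so the proxy signal is not drowned by the trend
  ic <- cell_of(obs)
  n_adj <- min(length(covariates), max(0, floor(nrow(obs) / 15)), 5)
  adj <- NULL
  if (n_adj > 0) {
    adj <- as.data.frame(lapply(covariates[seq_len(n_adj)],
                                function(cv) cv$values[ic]))
    names(adj) <- paste0("adj", seq_len(n_adj))
  }
  sel_r <- select_buffer_radius(candidate_radii_km, obs, sites,
                                covariates = adj)
  radius <- sel_r$radius_km
  dmin <- config$cell_size_km / 2
  prox_obs <- build_source_proxy(sites, obs, radius, d_min = dmin)
  prox_tar <- build_source_proxy(sites, co, radius, d_min = dmin)

  # (3) covariate stack + OOB selection
  Xo <- data.frame(prob = p_obs, proxy = prox_obs)
  Xt <- data.frame(prob = p_tar, proxy = prox_tar)
  for (nm in names(covariates)) {
    Xo[[nm]] <- covariates[[nm]]$values[ic]
    Xt[[nm]] <- as.vector(covariates[[nm]]$values)
  }
  sel <- select_covariates_oob(ylog, Xo, num_trees = num_trees, seed = seed)

  # (4) random-forest residual kriging on the selected stack
  oo <- obs
  oo$value <- ylog
  rk <- residual_krige(oo, Xo[sel$selected], Xt[sel$selected],
                       co[, c("x_km", "y_km")], trend = trend,
                       family = "spherical", num_trees = num_trees,
                       seed = seed)
  vals <- pmax(exp(rk$pred), 0)
  map <- raster_field(matrix(vals, config$grid_ny, config$grid_nx),
                      config$cell_size_km)
  cv <- NULL
  if (run_loocv) {
    cv <- loocv_residual_krige(oo, Xo[sel$selected], trend = trend,
                               family = "spherical",
                               num_trees = num_trees, seed = seed)
  }
  list(map = map, prob = raster_field(matrix(p_tar, config$grid_ny,
                                             config$grid_nx),
                                      config$cell_size_km),
       radius_km = radius, radius_aic = sel_r$aic,
       selected = sel$selected, oob_path = sel$oob_path,
       resid_model = rk$resid_model, loocv = cv)
}

#' Leave-one-out cross-validation of residual kriging
#'
#' Refits the trend on each fold's n-1 points; the residual variogram is
#' fitted once on the full-data residuals and reused across folds (refitting
#' per fold is available with `refit_variogram = TRUE`).
#'
#' @param obs `observation_set` (values already on the modelling scale)
#' @param X covariates at the observations
#' @param trend,family,num_trees,seed as in [residual_krige()]
#' @param refit_variogram refit the residual variogram inside each fold
#' @return [loocv()] report
#' @export
loocv_residual_krige <- function(obs, X, trend = "linear",
                                 family = "spherical", num_trees = 500,
                                 seed = 1L, refit_variogram = FALSE) {
  X <- as.data.frame(X)
  vm0 <- NULL
  if (!refit_variogram) {
    fit0 <- fit_trend(obs$value, X, trend, num_trees, seed)
    res0 <- obs$value - predict_trend(fit0, X)
    robs <- obs; robs$value <- res0
    span <- max(dist_xy(cbind(obs$x_km, obs$y_km)))
    emp <- empirical_variogram(robs, seq(0, span / 2, length.out = 13))
    vm0 <- if (nrow(emp) >= 3) fit_variogram(emp, family) else
      variogram_model(family, max(stats::var(res0), 1e-10), 1e-8, span / 4)
  }
  xcols <- names(X)
  obsX <- cbind(obs, X)
  loocv(obsX, function(tr, te) {
    fit <- fit_trend(tr$value, tr[xcols], trend, num_trees, seed)
    mu_tr <- predict_trend(fit, tr[xcols])
    mu_te <- predict_trend(fit, te[xcols])
    res <- tr$value - mu_tr
    rtr <- tr; rtr$value <- res
    vm <- vm0
    if (is.null(vm)) {
      span <- max(dist_xy(cbind(tr$x_km, tr$y_km)))
      emp <- empirical_variogram(rtr, seq(0, span / 2, length.out = 13))
      vm <- fit_variogram(emp, family)
    }
    if (vm$nugget + vm$psill < 1e-12) return(mu_te + mean(res))
    mu_te + ordinary_krige(rtr, vm, te[, c("x_km", "y_km")])$pred
  })
}
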