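#' Distance-weighted emission proxy
#'
#' Disaggregates the emission raster in a buffer (default 20 km) around each
#' target location: proxy(x) = sum over emission cells whose centroid lies
#' within the radius of emission * 1/max(d, d_min). Locations with an empty
#' buffer get proxy 0 with a warning. Scaling the emission raster by k scales
#' every proxy by k.
#'
#' @param emission emission `raster_field` (mass/yr per cell)
#' @param locations data.frame with x_km, y_km
#' @param radius_km buffer radius, default 20
#' @param d_min distance floor (default half a cell width)
#' @return numeric proxy per location
#' @export
build_emission_proxy <- function(emission, locations, radius_km = 20,
                                 d_min = emission$cell_size_km / 2) {
  co <- raster_coords(emission)
  D <- dist_xy(cbind(locations$x_km, locations$y_km),
               cbind(co$x_km, co$y_km))
  W <- 1 / pmax(D, d_min)
  W[D > radius_km] <- 0
  if (any(rowSums(W > 0) == 0)) warning("location(s) with empty buffer; proxy 0")
  drop(W %*% as.vector(emission$values))
}

#' Drift model selection for air concentrations
#'
#' Fits linear models of the station annual means on candidate subsets of
#' {emission proxy, altitude, population} (the intercept-only model is always
#' a candidate) and compares them by leave-one-out ME and RMSE, overall and
#' by station type; the subset minimizing LOOCV RMSE wins. Collinear terms
#' are dropped by the least-squares fit itself (NA coefficients) with a
#' warning.
#'
#' @param obs `observation_set` of station annual means
#' @param X data.frame with columns `proxy`, `altitude`, `population` at the
#'   stations
#' @param candidates list of character vectors (term subsets); default: all
#'   subsets of the three terms
#' @param parsimony_tol relative RMSE tolerance of the parsimony rule: the
#'   smallest subset whose LOOCV RMSE is within this fraction of the minimum
#'   wins (a one-standard-error-style rule that keeps noise terms out)
#' @return list with `terms` (winning subset), `fit` (lm on all data),
#'   `table` (per-candidate LOOCV ME/RMSE), `by_type` for the winner
#' @export
fit_drift <- function(obs, X, candidates = NULL, parsimony_tol = 0.02) {
  X <- as.data.frame(X)
  allt <- names(X)
  if (is.null(candidates)) {
    candidates <- unlist(lapply(0:length(allt), function(k)
      utils::combn(allt, k, simplify = FALSE)), recursive = FALSE)
  }
  obsX <- cbind(obs, X)
  score <- lapply(candidates, function(tm) {
    cv <- loocv(obsX, function(tr, te) {
      if (length(tm) == 0) return(mean(tr$value))
      d <- cbind(.y = tr$value, tr[tm])
      f <- stats::lm(.y ~ ., data = d)
      if (anyNA(stats::coef(f))) warning("collinear drift terms dropped")
      unname(stats::predict(f, newdata = te[tm]))
    })
    data.frame(terms = paste(tm, collapse = "+"), me = cv$me, rmse = cv$rmse)
  })
  tab <- do.call(rbind, score)
  # parsimony: among subsets within tol of the best RMSE, take the smallest
  # (ties by RMSE)
  nterms <- lengths(candidates)
  adm <- which(tab$rmse <= min(tab$rmse) * (1 + parsimony_tol))
  best <- adm[order(nterms[adm], tab$rmse[adm])][1]
  tm <- candidates[[best]]
  fit <- if (length(tm) == 0) stats::lm(value ~ 1, data = obsX) else
    stats::lm(stats::reformulate(tm, "value"), data = obsX)
  cvb <- loocv(obsX, function(tr, te) {
    if (length(tm) == 0) return(mean(tr$value))
    d <- cbind(.y = tr$value, tr[tm])
    unname(stats::predict(stats::lm(.y ~ ., data = d), newdata = te[tm]))
  })
  list(terms = tm, fit = fit, table = tab, by_type = cvb$by_type,
       loocv = cvb)
}

#' Map one year of air concentrations
#'
#' Regression kriging: the selected drift (linear in the chosen terms) is
#' evaluated on the grid, and the station residuals are kriged with an
#' exponential variogram. A leave-one-out report for the full predictor is
#' attached.
#'
#' @param obs station `observation_set`
#' @param X drift covariates at the stations (`proxy`, `altitude`,
#'   `population`)
#' @param X_target same columns on the grid cells
#' @param config `scenario_config` (grid geometry)
#' @param terms drift terms to use; `NULL` selects by [fit_drift()]
#' @return list with `map` (`raster_field`), `terms`, `drift`, `resid_model`,
#'   `loocv`
#' @export
map_air_year <- function(obs, X, X_target, config, terms = NULL) {
  X <- as.data.frame(X); X_target <- as.data.frame(X_target)
  sel <- if (is.null(terms)) fit_drift(obs, X) else
    list(terms = terms, table = NULL)
  tm <- sel$terms
  co <- raster_coords(config)
  rk <- residual_krige(obs, X[tm], X_target[tm], co[, c("x_km", "y_km")],
                       trend = "linear", family = "exponential")
  cv <- loocv_residual_krige(obs, X[tm], trend = "linear",
                             family = "exponential")
  map <- raster_field(matrix(pmax(rk$pred, 0), config$grid_ny, config$grid_nx),
                      config$cell_size_km)
  list(map = map, terms = tm, selection = sel$table,
       drift = rk$trend, resid_model = rk$resid_model, loocv = cv)
}

#' Accuracy-weighted combination of yearly maps
#'
#' Cellwise weighted mean of the yearly concentration maps with
#' inverse-variance weights w_y proportional to 1/RMSE_y^2 (normalized to
#' one), so the more accurate year dominates; masks are OR-combined.
#'
#' @param maps list of `raster_field`s on the same grid
#' @param rmse numeric LOOCV RMSE per year (> 0)
#' @return a `raster_field`
#' @export
combine_years <- function(maps, rmse) {
  stopifnot(length(maps) == length(rmse), all(rmse > 0))
  dm <- dim(maps[[1]]$values)
  for (mp in maps) if (!identical(dim(mp$values), dm)) stop("mismatched grids")
  w <- (1 / rmse^2) / sum(1 / rmse^2)
  v <- Reduce(`+`, Map(function(mp, wi) wi * mp$values, maps, w))
  mm <- Reduce(`|`, lapply(maps, `[[`, "mask_missing"))
  mi <- Reduce(`|`, lapply(maps, `[[`, "mask_invalid"))
  out <- raster_field(v, maps[[1]]$cell_size_km, mm, mi)
  attr(out, "weights") <- w
  out
}

#' Validity mask for the air map
#'
#' Flags cells where the air estimate is not considered relevant: altitude
#' above 1800 m AND population density below 30 persons/km^2 (high-altitude,
#' sparsely inhabited areas with no monitoring support). Population density
#' is the population raster divided by the cell area.
#'
#' @param altitude altitude `raster_field` (m)
#' @param population population `raster_field` (persons per cell)
#' @param alt_limit_m altitude threshold, default 1800
#' @param density_limit density threshold, default 30 persons/km^2
#' @return logical matrix, `TRUE` = invalid
#' @export
validity_mask <- function(altitude, population, alt_limit_m = 1800,
                          density_limit = 30) {
  if (!identical(dim(altitude$values), dim(population$values)))
    stop("rasters not aligned")
  area <- altitude$cell_size_km^2
  dens <- population$values / area
  altitude$values > alt_limit_m & dens < density_limit
}
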