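#' Write receptor profiles to a YAML config
#'
#' @param receptors list of `receptor_profile`s
#' @param path output file
#' @export
write_receptors <- function(receptors, path) {
  yaml::write_yaml(lapply(receptors, function(r) {
    r <- unclass(r)
    r$veg_intake <- as.list(r$veg_intake)
    r
  }), path)
  invisible(path)
}

#' Read receptor profiles written by [write_receptors()]
#'
#' @param path YAML file
#' @return list of `receptor_profile`s
#' @export
read_receptors <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r)
    receptor_profile(r$age_class, r$body_weight, r$water_intake,
                     r$soil_ingestion, r$inhalation_rate,
                     unlist(r$veg_intake), r$self_consumption,
                     r$exposure_duration, r$lifetime))
}

#' Run the full exposure pipeline on a synthetic scenario
#'
#' Executes every stage in order — scenario generation, water imputation
#' (bootstrap EM), segments-of-influence unit means, network aggregation and
#' rasterization, soil mapping (indicator kriging + source proxy + OOB
#' selection + random-forest residual kriging), two years of air mapping
#' (drift selection + exponential regression kriging) combined by
#' inverse-RMSE^2 weights with the validity mask, and the multimedia
#' LADD/EIR maps. All randomness flows from the config's master seed via
#' fixed offsets; a rerun with the same config reproduces the outputs. Stage
#' outputs and diagnostics are returned in one list and, when `out_dir` is
#' given, persisted (rasters and tables as CSV, a JSON run manifest tying
#' them together).
#'
#' @param config a `scenario_config`
#' @param m number of imputations (default 8)
#' @param out_dir optional output directory
#' @param num_trees random-forest size for the soil stage
#' @param run_loocv run the soil leave-one-out report (the air stages always
#'   run theirs, they are cheap)
#' @param verbose log stage progress
#' @return list with all stage outputs (`scenario`, `imputed`, `water`,
#'   `soil`, `air`, `exposure`, `manifest`)
#' @export
run_pipeline <- function(config, m = 8, out_dir = NULL, num_trees = 300,
                         run_loocv = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  manifest <- list(seed = seed, m = m,
                   grid = c(config$grid_ny, config$grid_nx),
                   cell_size_km = config$cell_size_km)

  say("[scenario] generating synthetic inputs (seed %d)", seed)
  wat <- simulate_water_panel(config, seed = seed)
  soi <- simulate_soil_survey(config, seed = seed + 1L)
  air1 <- simulate_air_year(config, year_effect = 1, seed = seed + 2L)
  air2 <- simulate_air_year(config, year_effect = 0, seed = seed + 3L)
  receptors <- make_receptors(config)
  manifest$water_censoring <- mean(wat$panel$censored)
  manifest$soil_censoring <- mean(soi$obs$censored)

  say("[impute] bootstrap-EM multiple imputation, m=%d", m)
  imp <- em_bootstrap_impute(wat$panel, m = m, seed = seed + 10L)

  say("[water] unit means, network aggregation, rasterization")
  um <- unit_means(imp, window = config$date_window)
  mc <- municipality_concentration(um, wat$network)
  cmap <- municipality_cell_map(config, wat$municipality_seeds)
  wras <- rasterize_municipalities(mc, cmap, config$cell_size_km)
  manifest$water_missing_cells <- sum(wras$value$mask_missing)

  say("[soil] indicator kriging, proxy, OOB selection, RF residual kriging")
  names(soi$covariates) <- paste0("cov", seq_along(soi$covariates))
  smap <- map_soil(soi$obs, soi$covariates, soi$sites, config,
                   num_trees = num_trees, seed = seed + 20L,
                   run_loocv = run_loocv)
  manifest$soil_radius_km <- smap$radius_km
  manifest$soil_selected <- smap$selected
  if (!is.null(smap$loocv))
    manifest$soil_loocv <- c(me = smap$loocv$me, rmse = smap$loocv$rmse)

  say("[air] drift selection + exponential regression kriging, two years")
  co <- raster_coords(config)
  amaps <- lapply(list(air1, air2), function(ay) {
    st_cells <- cell_index(ay$obs, config)
    Xs <- data.frame(proxy = ay$proxy,
                     altitude = ay$altitude$values[st_cells],
                     population = ay$population$values[st_cells])
    Xt <- data.frame(proxy = build_emission_proxy(ay$emission, co),
                     altitude = as.vector(ay$altitude$values),
                     population = as.vector(ay$population$values))
    map_air_year(ay$obs, Xs, Xt, config)
  })
  rmses <- vapply(amaps, function(a) a$loocv$rmse, numeric(1))
  acomb <- combine_years(lapply(amaps, `[[`, "map"), rmses)
  vm <- validity_mask(air1$altitude, air1$population)
  acomb$mask_invalid <- acomb$mask_invalid | vm
  manifest$air_terms <- lapply(amaps, `[[`, "terms")
  manifest$air_rmse <- rmses
  manifest$air_weights <- as.numeric(attr(acomb, "weights"))
  manifest$air_invalid_cells <- sum(vm)

  say("[exposure] LADD/EIR maps for %d receptors", length(receptors))
  expo <- map_exposure(wras$value, smap$map, acomb, receptors)

  out <- list(scenario = list(water = wat, soil = soi, air = list(air1, air2),
                              receptors = receptors),
              imputed = imp, water = c(wras, list(unit_means = um,
                                                  municipal = mc)),
              soil = smap,
              air = list(years = amaps, combined = acomb, validity = vm),
              exposure = expo, manifest = manifest)
  if (!is.null(out_dir)) persist_run(out, out_dir)
  out
}

cell_index <- function(pts, config) {
  col <- pmin(pmax(ceiling(pts$x_km / config$cell_size_km), 1), config$grid_nx)
  row <- pmin(pmax(ceiling(pts$y_km / config$cell_size_km), 1), config$grid_ny)
  cbind(row, col)
}

persist_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_raster_csv(run$water$value, fp("water_concentration.csv"))
  write_raster_csv(run$water$sd, fp("water_uncertainty.csv"))
  write_raster_csv(run$soil$map, fp("soil_concentration.csv"))
  write_raster_csv(run$soil$prob, fp("soil_exceedance_probability.csv"))
  write_raster_csv(run$air$combined, fp("air_concentration.csv"))
  utils::write.csv(run$water$unit_means, fp("unit_means.csv"),
                   row.names = FALSE)
  utils::write.csv(run$water$municipal, fp("municipality_concentration.csv"),
                   row.names = FALSE)
  for (rc in names(run$exposure)) {
    write_raster_csv(run$exposure[[rc]]$eir$total,
                     fp(sprintf("eir_total_%s.csv", rc)))
    utils::write.csv(run$exposure[[rc]]$contributions,
                     fp(sprintf("contributions_%s.csv", rc)),
                     row.names = FALSE)
  }
  write_receptors(run$scenario$receptors, fp("receptors.yaml"))
  jsonlite::write_json(run$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render the total-risk map with uncertainty overlays
#'
#' Choropleth of total EIR (printed on the x10^6 scale) with the two overlay
#' styles of the final inequality map: grey borders on cells where water
#' data were missing, and a black cross-hatch (point hatching) on cells
#' outside the air validity limits.
#'
#' @param eir total-EIR `raster_field` (raw, unscaled risk)
#' @param path optional file to save (png)
#' @return the ggplot object
#' @export
render_risk_map <- function(eir, path = NULL) {
  d <- raster_coords(eir)
  d$eir6 <- as.vector(eir$values) * 1e6
  d$missing <- as.vector(eir$mask_missing)
  d$invalid <- as.vector(eir$mask_invalid)
  d$eir6[d$missing | d$invalid] <- NA
  g <- ggplot2::ggplot(d, ggplot2::aes(x = x_km, y = y_km)) +
    ggplot2::geom_tile(ggplot2::aes(fill = eir6)) +
    ggplot2::scale_fill_viridis_c(name = "Total EIR (x10^6)",
                                  na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km",
                  title = "Excess individual risk (x10^6)",
                  subtitle = "grey border: water data missing; cross-hatch: outside air validity limits") +
    ggplot2::theme_minimal()
  if (any(d$missing)) {
    g <- g + ggplot2::geom_tile(data = d[d$missing, ], fill = NA,
                                colour = "grey40", linewidth = 0.4)
  }
  if (any(d$invalid)) {
    g <- g + ggplot2::geom_point(data = d[d$invalid, ], shape = 4,
                                 size = 0.8, colour = "black")
  }
  if (!is.null(path)) ggplot2::ggsave(path, g, width = 7, height = 6, dpi = 120)
  g
}
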