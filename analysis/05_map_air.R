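#!/usr/bin/env Rscript
# Air stage: emission proxy in a 20 km buffer, LOOCV-based drift-term
# selection (altitude enters only in the year with a real altitude effect),
# exponential-variogram regression kriging, inverse-RMSE^2 combination of
# the two years, validity mask (altitude > 1800 m AND density < 30/km^2).

source(file.path("analysis", "_common.R"))
cfg <- analysis_config()
out <- results_dir("rasters")
tabs <- results_dir("tables")

co <- raster_coords(cfg)
years <- list(y1 = simulate_air_year(cfg, year_effect = 1,
                                     seed = cfg$seed + 2L),
              y2 = simulate_air_year(cfg, year_effect = 0,
                                     seed = cfg$seed + 3L))

maps <- list(); rmses <- c()
for (nm in names(years)) {
  ay <- years[[nm]]
  ic <- cbind(pmin(pmax(ceiling(ay$obs$y_km / cfg$cell_size_km), 1),
                   cfg$grid_ny),
              pmin(pmax(ceiling(ay$obs$x_km / cfg$cell_size_km), 1),
                   cfg$grid_nx))
  Xs <- data.frame(proxy = ay$proxy, altitude = ay$altitude$values[ic],
                   population = ay$population$values[ic])
  Xt <- data.frame(proxy = build_emission_proxy(ay$emission, co),
                   altitude = as.vector(ay$altitude$values),
                   population = as.vector(ay$population$values))
  am <- map_air_year(ay$obs, Xs, Xt, cfg)
  maps[[nm]] <- am$map
  rmses[nm] <- am$loocv$rmse
  write.csv(am$selection, file.path(tabs, paste0("air_terms_", nm, ".csv")),
            row.names = FALSE)
  message(sprintf("%s: drift terms {%s}; LOOCV RMSE %.3f ng/m3", nm,
                  paste(am$terms, collapse = ", "), am$loocv$rmse))
}

comb <- combine_years(maps, rmses)
vm <- validity_mask(years$y1$altitude, years$y1$population)
comb$mask_invalid <- comb$mask_invalid | vm
write_raster_csv(comb, file.path(out, "air_concentration.csv"))
message(sprintf("year weights %.3f / %.3f; %d cells outside validity limits",
                attr(comb, "weights")[1], attr(comb, "weights")[2], sum(vm)))
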