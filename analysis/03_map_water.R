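#!/usr/bin/env Rscript
# Water stage: multiple imputation of the censored panel (m = 8), multi-annual
# unit means with segments-of-influence weights, population-weighted
# aggregation through the distribution network, rasterization to the 3 km
# reference grid with an across-imputation uncertainty layer.

source(file.path("analysis", "_common.R"))
cfg <- analysis_config()
out <- results_dir("rasters")
tabs <- results_dir("tables")

wat <- simulate_water_panel(cfg)
message(sprintf("panel: %d records, %.1f%% censored", nrow(wat$panel),
                100 * mean(wat$panel$censored)))

imp <- em_bootstrap_impute(wat$panel, m = 8, seed = cfg$seed + 10L)
um <- unit_means(imp, window = cfg$date_window)
mc <- municipality_concentration(um, wat$network)
cmap <- municipality_cell_map(cfg, wat$municipality_seeds)
ras <- rasterize_municipalities(mc, cmap, cfg$cell_size_km)

write.csv(um, file.path(tabs, "water_unit_means.csv"), row.names = FALSE)
write.csv(mc, file.path(tabs, "water_municipalities.csv"), row.names = FALSE)
write_raster_csv(ras$value, file.path(out, "water_concentration.csv"))
write_raster_csv(ras$sd, file.path(out, "water_uncertainty.csv"))

message(sprintf(
  "water raster: %d/%d cells served; median concentration %.3g mg/L; %d municipalities missing",
  sum(!ras$value$mask_missing), length(ras$value$values),
  median(ras$value$values[!ras$value$mask_missing]), sum(mc$missing)))
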