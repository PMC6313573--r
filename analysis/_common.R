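# Shared settings for the analysis drivers. Every script regenerates its
# inputs deterministically from this config, so the scripts can be run in
# any order (01 -> 06 reads naturally).

library(geoexpose)

MASTER_SEED <- 20260101L

analysis_config <- function() {
  scenario_config(grid_nx = 40, grid_ny = 40, cell_size_km = 3,
                  n_units = 200, n_municipalities = 120,
                  n_stations = 76, n_polluted_sites = 12,
                  soil_spacing_km = 6, seed = MASTER_SEED)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
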