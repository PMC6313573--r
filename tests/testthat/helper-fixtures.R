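# shared fixture builders (all generated in code; no stored data)

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny complete two-substance panel with known values
make_tiny_panel <- function(values1, values2, dl = 1) {
  n <- length(values1)
  dates <- as.Date("2005-06-01") + seq(0, by = 30, length.out = n)
  censored_panel(data.frame(
    obs_id = rep(seq_len(n), 2),
    unit_id = rep(1L, 2 * n),
    date = rep(dates, 2),
    substance = rep(c("S1", "S2"), each = n),
    value = c(values1, values2),
    censored = FALSE, dl = dl))
}

# raster index of point coordinates on a config grid
cells_of <- function(pts, config) {
  col <- pmin(pmax(ceiling(pts$x_km / config$cell_size_km), 1), config$grid_nx)
  row <- pmin(pmax(ceiling(pts$y_km / config$cell_size_km), 1), config$grid_ny)
  cbind(row, col)
}

# station covariates for an air-year scenario
air_covariates <- function(ay, config) {
  ic <- cells_of(ay$obs, config)
  data.frame(proxy = ay$proxy,
             altitude = ay$altitude$values[ic],
             population = ay$population$values[ic])
}
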