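#' Segments-of-influence temporal weights
#'
#' Each observation owns the interval between the midpoints of its flanking
#' gaps (the window edges for the first and last observation); its weight is
#' the number of days it owns divided by the total window length. Weights sum
#' to one for any date pattern.
#'
#' @param dates sorted observation dates inside the window
#' @param window length-2 vector (Date or numeric days), start <= end,
#'   spanning at least one day
#' @return numeric weights, one per date, summing to 1
#' @export
segment_weights <- function(dates, window) {
  d <- as.numeric(as.Date(dates))
  w0 <- as.numeric(as.Date(window))
  if (length(d) == 0) stop("empty date list")
  if (diff(w0) <= 0) stop("window must span at least one day")
  if (is.unsorted(d)) stop("dates must be sorted")
  if (any(d < w0[1] | d > w0[2])) stop("dates outside window")
  cuts <- c(w0[1], (d[-1] + d[-length(d)]) / 2, w0[2])
  diff(cuts) / diff(w0)
}

#' Multi-annual weighted mean concentration of one distribution unit
#'
#' Per imputation, the segments-of-influence weighted mean of the unit's
#' records over the analysis window; pooled as the mean over the m
#' imputations, with the across-imputation standard deviation as the
#' uncertainty.
#'
#' @param imputed an `imputed_panel_set` (or a single complete panel)
#' @param unit_id the unit
#' @param window analysis window (default the panel's date range)
#' @param substance substance to average (default the first)
#' @return list with `mean`, `sd` (0 for a single panel), `n_obs`
#' @export
unit_mean <- function(imputed, unit_id, window = NULL, substance = NULL) {
  panels <- if (inherits(imputed, "imputed_panel_set")) imputed$panels
            else list(imputed)
  p1 <- panels[[1]]
  if (is.null(substance)) substance <- sort(unique(p1$substance))[1]
  sel <- p1$unit_id == unit_id & p1$substance == substance
  if (!any(sel)) stop("unit absent from panel: ", unit_id)
  if (is.null(window)) window <- range(p1$date)
  ord <- order(p1$date[sel])
  dts <- p1$date[sel][ord]
  w <- segment_weights(dts, window)
  means <- vapply(panels, function(pp) {
    sum(w * pp$value[sel][ord])
  }, numeric(1))
  list(mean = mean(means),
       sd = if (length(means) > 1) stats::sd(means) else 0,
       n_obs = sum(sel))
}

#' Unit means for every unit in a panel set
#'
#' @inheritParams unit_mean
#' @return data.frame with unit_id, mean, sd, n_obs
#' @export
unit_means <- function(imputed, window = NULL, substance = NULL) {
  p1 <- if (inherits(imputed, "imputed_panel_set")) imputed$panels[[1]] else imputed
  ids <- sort(unique(p1$unit_id))
  out <- lapply(ids, function(u) {
    um <- unit_mean(imputed, u, window, substance)
    data.frame(unit_id = u, mean = um$mean, sd = um$sd, n_obs = um$n_obs)
  })
  do.call(rbind, out)
}

#' Population-weighted municipality concentrations
#'
#' Aggregates unit means through the distribution network: each
#' municipality's concentration is the mean of its serving units' values
#' weighted by the population each unit serves in that municipality
#' (weights normalized per municipality). Municipalities with zero total
#' served population are returned with `missing = TRUE`. The uncertainty
#' layer is aggregated with the same weights.
#'
#' @param umeans data.frame from [unit_means()]
#' @param network data.frame with unit_id, municipality_id, served_population
#' @return data.frame with municipality_id, value, sd, missing
#' @export
municipality_concentration <- function(umeans, network) {
  if (any(network$served_population < 0)) stop("negative served population")
  miss <- setdiff(network$unit_id, umeans$unit_id)
  if (length(miss)) stop("units without a mean: ", paste(miss, collapse = ","))
  net <- merge(network, umeans, by = "unit_id")
  out <- do.call(rbind, lapply(split(net, net$municipality_id), function(g) {
    tot <- sum(g$served_population)
    if (tot <= 0) {
      return(data.frame(municipality_id = g$municipality_id[1],
                        value = NA_real_, sd = NA_real_, missing = TRUE))
    }
    w <- g$served_population / tot
    data.frame(municipality_id = g$municipality_id[1],
               value = sum(w * g$mean), sd = sqrt(sum((w * g$sd)^2)),
               missing = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign grid cells to municipalities (Voronoi tessellation)
#'
#' Each cell belongs to the municipality whose seed point is nearest to the
#' cell center (the Voronoi partition restricted to cell centers); a
#' synthetic stand-in for real municipal boundary polygons.
#'
#' @param config a `scenario_config` (grid geometry)
#' @param seeds data.frame with municipality_id, x_km, y_km
#' @return integer matrix (ny x nx) of municipality ids
#' @export
municipality_cell_map <- function(config, seeds) {
  co <- raster_coords(config)
  D <- dist_xy(cbind(co$x_km, co$y_km), cbind(seeds$x_km, seeds$y_km))
  ids <- seeds$municipality_id[max.col(-D, ties.method = "first")]
  matrix(ids, config$grid_ny, config$grid_nx)
}

#' Rasterize municipality concentrations to the reference grid
#'
#' Every cell takes exactly its municipality's value (no smoothing); cells of
#' municipalities with missing concentrations get `mask_missing = TRUE` — the
#' grey-border overlay of the final risk map. An uncertainty raster built
#' from the across-imputation sd is attached.
#'
#' @param mconc data.frame from [municipality_concentration()]
#' @param cell_map matrix from [municipality_cell_map()]
#' @param cell_size_km cell size
#' @return list with `value` and `sd` `raster_field`s
#' @export
rasterize_municipalities <- function(mconc, cell_map, cell_size_km = 3) {
  ix <- match(as.vector(cell_map), mconc$municipality_id)
  # municipalities absent from the concentration table are unserved -> missing
  v <- mconc$value[ix]
  s <- mconc$sd[ix]
  mm <- is.na(ix) | mconc$missing[ix] | is.na(v)
  v[mm] <- 0; s[mm] <- 0
  dm <- dim(cell_map)
  list(value = raster_field(matrix(v, dm[1], dm[2]), cell_size_km,
                            mask_missing = matrix(mm, dm[1], dm[2])),
       sd = raster_field(matrix(s, dm[1], dm[2]), cell_size_km,
                         mask_missing = matrix(mm, dm[1], dm[2])))
}
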