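#' Receptor profile
#'
#' Age-class-specific exposure parameters. Intake rates are daily averages;
#' the two standard classes (children 0-17 y, adults 17-70 y) have exposure
#' durations partitioning the 70-year lifetime. All rates must be
#' nonnegative; the self-consumption fraction (share of vegetable intake that
#' is homegrown, hence exposed to local contamination) lies in [0, 1].
#'
#' @param age_class `"child_0_17"` or `"adult_17_70"` (free labels allowed)
#' @param body_weight kg
#' @param water_intake L/day
#' @param soil_ingestion mg/day (incidental)
#' @param inhalation_rate m^3/day
#' @param veg_intake named vector, g fresh weight/day per food category
#' @param self_consumption fraction in [0, 1]
#' @param exposure_duration years
#' @param lifetime years, default 70
#' @return list of class `receptor_profile`
#' @export
receptor_profile <- function(age_class, body_weight, water_intake,
                             soil_ingestion, inhalation_rate, veg_intake,
                             self_consumption, exposure_duration,
                             lifetime = 70) {
  rates <- c(body_weight, water_intake, soil_ingestion, inhalation_rate,
             veg_intake, exposure_duration, lifetime)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (body_weight <= 0) stop("body weight must be > 0")
  if (self_consumption < 0 || self_consumption > 1)
    stop("self_consumption must be in [0, 1]")
  structure(list(age_class = age_class, body_weight = body_weight,
                 water_intake = water_intake, soil_ingestion = soil_ingestion,
                 inhalation_rate = inhalation_rate, veg_intake = veg_intake,
                 self_consumption = self_consumption,
                 exposure_duration = exposure_duration, lifetime = lifetime),
            class = "receptor_profile")
}

#' Default vegetable transfer parameters
#'
#' Simplified air + soil to vegetable transfer: an atmospheric deposition
#' term and a root-uptake term (see [veg_transfer()]). These are
#' order-of-magnitude defaults for a semivolatile particle-bound PAH, not
#' values from any toxicological authority; real applications must supply
#' their own.
#'
#' @return list with `deposition_velocity_m_day`, `interception`,
#'   `weathering_per_day`, `yield_kg_m2`, `soil_to_plant` (named per
#'   category)
#' @export
default_transfer_params <- function() {
  list(deposition_velocity_m_day = 100,   # ~0.12 cm/s
       interception = 0.3,
       weathering_per_day = 0.1,          # ~7-day weathering half-life
       yield_kg_m2 = c(leaf = 2, root = 3, fruit = 2.5),
       soil_to_plant = c(leaf = 5e-3, root = 5e-3, fruit = 1e-3))
}

#' Air + soil to homegrown-vegetable transfer
#'
#' C_veg = deposition term + root-uptake term, linear in each input:
#' deposition = C_air (mg/m^3) * v_dep * interception /
#' (yield * weathering); root uptake = C_soil * soil-to-plant factor. Air
#' enters in ng/m^3 and is converted internally.
#'
#' @param air ng/m^3 (scalar or vector)
#' @param soil mg/kg (same length)
#' @param params from [default_transfer_params()]
#' @return matrix (length(air) x categories) of mg/kg fresh weight
#' @export
veg_transfer <- function(air, soil, params = default_transfer_params()) {
  if (any(params$yield_kg_m2 <= 0)) stop("yields must be > 0")
  cats <- names(params$yield_kg_m2)
  air_mg <- air * 1e-6
  dep <- outer(air_mg * params$deposition_velocity_m_day * params$interception,
               1 / (params$yield_kg_m2 * params$weathering_per_day))
  root <- outer(soil, params$soil_to_plant[cats])
  out <- dep + root
  colnames(out) <- cats
  out
}

#' Lifetime Average Daily Doses per pathway
#'
#' LADD_pathway = C * intake_rate * exposure_duration /
#' (body_weight * lifetime), in mg per kg body weight per day, with unit
#' conversions: air ng/m^3 -> mg/m^3, soil ingestion mg/day -> kg/day,
#' vegetable intakes g/day -> kg/day. Homegrown vegetable intake is the
#' category intake scaled by the self-consumption fraction; commercial
#' intake by its complement, at the spatially constant commercial
#' concentrations.
#'
#' @param media list with `air` (ng/m^3), `soil` (mg/kg), `water` (mg/L),
#'   `veg` (matrix from [veg_transfer()] or named vector, mg/kg),
#'   `commercial` (named vector, mg/kg, constant); scalars or equal-length
#'   vectors
#' @param receptor a `receptor_profile`
#' @return list of class `dose_result` with `ladd` (named list per pathway,
#'   mg.kg-1.day-1); fill the risk slots with [compute_eir()]
#' @export
compute_ladd <- function(media, receptor) {
  if (any(unlist(media) < 0, na.rm = TRUE)) stop("negative concentrations")
  r <- receptor
  tf <- r$exposure_duration / (r$lifetime * r$body_weight)  # time/bw factor
  veg <- media$veg
  if (is.null(dim(veg))) veg <- matrix(veg, nrow = 1,
                                       dimnames = list(NULL, names(veg)))
  cats <- names(r$veg_intake)
  hg_int <- r$veg_intake * r$self_consumption * 1e-3        # kg/day
  cm_int <- r$veg_intake * (1 - r$self_consumption) * 1e-3
  ladd <- list(
    water = media$water * r$water_intake * tf,
    soil = media$soil * r$soil_ingestion * 1e-6 * tf,
    air_inhalation = media$air * 1e-6 * r$inhalation_rate * tf,
    homegrown_veg = drop(veg[, cats, drop = FALSE] %*% hg_int[cats]) * tf,
    commercial_food = sum(media$commercial[cats] * cm_int[cats]) * tf
  )
  structure(list(ladd = ladd, eir = NULL, contributions = NULL,
                 age_class = r$age_class),
            class = "dose_result")
}

#' Excess Individual Risk from the dose result
#'
#' Linear low-dose model: EIR_route = slope_factor_route * sum of that
#' route's LADDs; ingestion covers water, soil, homegrown and commercial
#' food, inhalation covers air. Total EIR is the sum over routes. Pathway
#' contributions (each pathway's share of total EIR, summing to one where
#' the total is positive) are filled in. Risk is dimensionless; map outputs
#' conventionally print it multiplied by 10^6.
#'
#' @param doses a `dose_result` from [compute_ladd()]
#' @param slope_factors named vector `c(ingestion = ..., inhalation = ...)`,
#'   in (mg.kg-1.day-1)^-1, both > 0
#' @return the `dose_result` with `eir` and `contributions` filled
#' @export
compute_eir <- function(doses, slope_factors = c(ingestion = 7.3,
                                                 inhalation = 3.9)) {
  if (any(slope_factors <= 0)) stop("slope factors must be > 0")
  ing_paths <- c("water", "soil", "homegrown_veg", "commercial_food")
  ing <- Reduce(`+`, doses$ladd[ing_paths]) * slope_factors["ingestion"]
  inh <- doses$ladd$air_inhalation * slope_factors["inhalation"]
  tot <- ing + inh
  sf_of <- c(water = "ingestion", soil = "ingestion",
             homegrown_veg = "ingestion", commercial_food = "ingestion",
             air_inhalation = "inhalation")
  contr <- lapply(names(doses$ladd), function(p)
    ifelse(tot > 0, slope_factors[sf_of[p]] * doses$ladd[[p]] / tot, NA_real_))
  names(contr) <- names(doses$ladd)
  doses$eir <- list(ingestion = unname(ing), inhalation = unname(inh),
                    total = unname(tot))
  doses$contributions <- contr
  doses
}

#' Map exposure on the reference grid
#'
#' Cellwise LADD and EIR for each receptor from the media rasters. Cells
#' missing in the water layer propagate `mask_missing`; cells invalid in the
#' air layer propagate `mask_invalid` (both also flag the total-EIR raster:
#' a cell compromised in any contributing medium is flagged, never silently
#' filled). A pathway-contribution summary over fully valid cells is
#' attached.
#'
#' @param water,soil,air `raster_field`s on the same grid (water mg/L, soil
#'   mg/kg, air ng/m^3)
#' @param receptors list of `receptor_profile`s
#' @param slope_factors as in [compute_eir()]
#' @param commercial named vector of commercial food concentrations (mg/kg)
#' @param transfer_params as in [veg_transfer()]
#' @return list per receptor: `ladd` (list of rasters per pathway), `eir`
#'   (rasters: ingestion, inhalation, total), `contributions` (data.frame
#'   over valid cells)
#' @export
map_exposure <- function(water, soil, air, receptors,
                         slope_factors = c(ingestion = 7.3, inhalation = 3.9),
                         commercial = c(leaf = 2e-3, root = 2e-3,
                                        fruit = 2e-3),
                         transfer_params = default_transfer_params()) {
  dm <- dim(water$values)
  if (!identical(dim(soil$values), dm) || !identical(dim(air$values), dm))
    stop("media rasters on different grids")
  mm <- water$mask_missing | soil$mask_missing | air$mask_missing
  mi <- water$mask_invalid | soil$mask_invalid | air$mask_invalid
  ok <- !(mm | mi)
  h <- water$cell_size_km
  veg <- veg_transfer(as.vector(air$values), as.vector(soil$values),
                      transfer_params)
  media <- list(air = as.vector(air$values), soil = as.vector(soil$values),
                water = as.vector(water$values), veg = veg,
                commercial = commercial)
  as_rf <- function(v) raster_field(matrix(v, dm[1], dm[2]), h, mm, mi)
  out <- lapply(receptors, function(r) {
    dr <- compute_eir(compute_ladd(media, r), slope_factors)
    ladd_r <- lapply(dr$ladd, function(v)
      as_rf(if (length(v) == 1) rep(v, prod(dm)) else v))
    eir_r <- lapply(dr$eir, function(v)
      as_rf(if (length(v) == 1) rep(v, prod(dm)) else v))
    contr <- vapply(dr$contributions, function(v) {
      vv <- if (length(v) == 1) rep(v, prod(dm)) else v
      mean(vv[ok], na.rm = TRUE)
    }, numeric(1))
    list(age_class = r$age_class, ladd = ladd_r, eir = eir_r,
         contributions = data.frame(pathway = names(contr),
                                    mean_share = unname(contr)))
  })
  names(out) <- vapply(receptors, `[[`, "", "age_class")
  out
}
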